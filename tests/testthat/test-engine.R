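# Adaptive deadline, timeout pool, scoring, and the session loop.

test_that("threshold update follows the 60-90% band with 10% steps", {
  p <- engine_params()
  expect_equal(update_threshold(rep(c(TRUE, FALSE), 8), 2000, p), 2200)   # 8/16
  expect_equal(update_threshold(c(rep(TRUE, 15), FALSE), 2000, p), 1800)  # 15/16
  expect_equal(update_threshold(rep(c(TRUE, TRUE, FALSE), c(6, 6, 4)), 2000, p), 2000)  # 12/16 = 0.75
  # boundary accuracies leave the threshold unchanged (strict inequalities)
  p10 <- engine_params(window_len = 10)
  expect_equal(update_threshold(rep(c(TRUE, FALSE), c(6, 4)), 2000, p10), 2000)  # 0.60
  expect_equal(update_threshold(rep(c(TRUE, FALSE), c(9, 1)), 2000, p10), 2000)  # 0.90
  # floor clamp
  expect_equal(update_threshold(rep(TRUE, 16), 320, p), 300)
  expect_error(update_threshold(rep(TRUE, 8), 2000, p), "16")
})

test_that("timeout pool cycles through eight targets, each twice", {
  withr::with_seed(5, {
    pool <- new_timeout_pool()
    first8 <- replicate(8, pool$draw())
    expect_equal(as.vector(table(first8)), rep(2L, 4))
    next8 <- replicate(8, pool$draw())
    expect_equal(as.vector(table(next8)), rep(2L, 4))
    expect_equal(as.vector(table(c(first8, next8))), rep(4L, 4))
  })
  draws_a <- withr::with_seed(11, replicate(20, new_timeout_pool()$draw()))
  draws_b <- withr::with_seed(11, replicate(20, new_timeout_pool()$draw()))
  expect_identical(draws_a, draws_b)
})

test_that("scoring awards 10 main-task and 3 evaluation points", {
  p <- engine_params()
  expect_equal(score_trial(FALSE, TRUE, TRUE, p), 13L)   # correct + good rating
  expect_equal(score_trial(FALSE, TRUE, NA, p), 10L)     # missing rating
  expect_equal(score_trial(TRUE, FALSE, TRUE, p), 3L)    # timeout, evaluated right
  expect_equal(score_trial(FALSE, FALSE, FALSE, p), 0L)  # error rated "correct"
  expect_equal(score_trial(TRUE, TRUE, FALSE, p), 0L)    # auto-correct, rated wrong
})

test_that("a perfect instant responder earns the maximum score without timeouts", {
  plan <- build_session(session_config(4, 32, seed = 8))
  log <- run_session(plan, perfect_responder(), seed = 8)
  expect_equal(nrow(log), 128)
  expect_equal(sum(log$is_timeout), 0)
  expect_true(all(log$is_correct))
  expect_equal(attr(log, "score"), attr(log, "max_score"))
  expect_equal(attr(log, "max_score"), 128 * 13)
})

test_that("an always-slow responder times out everywhere and drains balanced pools", {
  plan <- build_session(session_config(2, 32, seed = 3))
  log <- run_session(plan, never_responder(), seed = 3)
  expect_true(all(log$is_timeout))
  expect_true(all(is.na(log$rt_ms)))
  # each consecutive pool cycle of 8 timeouts shows each target twice
  for (cyc in split(log$chosen_target, (seq_len(64) - 1) %/% 8)) {
    expect_equal(as.vector(table(cyc)), rep(2L, 4))
  }
  expect_equal(sum(log$points_earned > 0), sum(!log$is_correct))  # "no" ratings
})

test_that("a 50%-accuracy responder drives a strictly x1.1 threshold staircase", {
  plan <- build_session(session_config(4, 32, seed = 6))
  log <- run_session(plan, coin_responder(), seed = 6)
  thr <- log$threshold_at_trial_ms
  changes <- which(diff(thr) != 0)
  expect_true(all(changes %% 16 == 0))
  at_windows <- thr[seq(1, 128, by = 16)]
  expect_equal(at_windows, 2000 * 1.1^(0:7))
})

test_that("session invariants hold for a stochastic agent", {
  cfg <- session_config(6, 32, seed = 14)
  log <- simulate_participant(cfg, agent_params(), seed = 14)
  thr <- log$threshold_at_trial_ms
  # threshold changes only at window boundaries, by -10%/0/+10% (clamped)
  expect_true(all(which(diff(thr) != 0) %% 16 == 0))
  steps <- thr[seq(17, 192, by = 16)] / thr[seq(1, 176, by = 16)]
  expect_true(all(vapply(steps, function(s) {
    isTRUE(all.equal(s, 0.9)) || isTRUE(all.equal(s, 1)) ||
      isTRUE(all.equal(s, 1.1)) || s > 1 / 1.1  # floor clamp
  }, logical(1))))
  # response types partition every block
  for (b in unique(log$block_index)) {
    blk <- log[log$block_index == b, ]
    expect_equal(sum(blk$is_timeout) +
                   sum(!blk$is_timeout & blk$is_correct) +
                   sum(!blk$is_timeout & !blk$is_correct), nrow(blk))
  }
  expect_lte(attr(log, "score"), attr(log, "max_score"))
  expect_true(all(is.na(log$rt_ms) == log$is_timeout))
  expect_true(all(log$rt_ms < log$threshold_at_trial_ms, na.rm = TRUE))
  # identical seeds reproduce the log byte for byte
  log2 <- simulate_participant(cfg, agent_params(), seed = 14)
  expect_identical(as.data.frame(log), as.data.frame(log2))
})

test_that("invalid responder output is a contract violation", {
  plan <- build_session(session_config(1, 32, seed = 2))
  bad_choice <- list(
    respond = function(trial, threshold_ms, block_index, prev) {
      list(choice = "banana", rt_ms = 100)
    },
    evaluate = function(outcome) "yes"
  )
  expect_error(run_session(plan, bad_choice, seed = 2), "unknown target")
  bad_rt <- list(
    respond = function(trial, threshold_ms, block_index, prev) {
      list(choice = trial$correct_target, rt_ms = NA_real_)
    },
    evaluate = function(outcome) "yes"
  )
  expect_error(run_session(plan, bad_rt, seed = 2), "rt_ms")
})
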