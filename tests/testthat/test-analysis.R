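# Behavioural measures computed from trial logs.

test_that("rates on a hand-counted toy log", {
  # 10 trials: 6 correct (5 confirmed, 1 rated "no"), 3 errors
  # (2 rated "no", 1 "yes"), 1 timeout
  log <- make_log(
    rule = 1L, correct = "ball", lure = "bird",
    chosen = c("ball", "ball", "ball", "ball", "ball", "ball",
               "chair", "chair", "bird", "ball"),
    timeout = c(rep(FALSE, 9), TRUE),
    rating = c("yes", "yes", "maybe_yes", "yes", "yes", "no",
               "no", "maybe_not", "yes", "no")
  )
  rr <- response_rates(log)$overall
  expect_equal(rr$correct_rate, 0.6)
  expect_equal(rr$error_rate, 0.3)
  expect_equal(rr$timeout_rate, 0.1)
  expect_equal(rr$error_detection_rate, 2 / 3)
  expect_equal(rr$correct_detection_rate, 5 / 6)
})

test_that("degenerate logs give missing (never zero) detection rates", {
  all_ok <- make_log(chosen = rep("ball", 8), rating = "yes")
  rr <- response_rates(all_ok)$overall
  expect_equal(rr$correct_detection_rate, 1)
  expect_true(is.na(rr$error_detection_rate))
  expect_error(response_rates(make_log()[0, ]), "non-empty")
})

test_that("rule-wise split matches a hand count", {
  log <- make_log(
    rule = rep(c(1L, 2L), each = 8),
    correct = "ball", lure = c(rep("bird", 8), rep("ball", 8)),
    chosen = c(rep("chair", 4), rep("ball", 4), rep("chair", 4), rep("ball", 4)),
    rating = c("no", rep("yes", 3), rep("yes", 4), rep("no", 4), rep("yes", 4))
  )
  sp <- split_by_rule(log)
  expect_equal(sp$n_errors, c(4L, 4L))
  expect_equal(sp$detection_rate, c(0.25, 1.0))
  expect_equal(sp$error_share, c(0.5, 0.5))
  # single-rule log: other rule reported as missing, no crash
  sp1 <- split_by_rule(log[log$required_rule == 1, ])
  expect_true(is.na(sp1$detection_rate[sp1$rule == 2]))
  expect_equal(sp1$detection_rate[sp1$rule == 1], 0.25)
})

test_that("PES/PCS on the worked 8-trial example", {
  # RTs 1000,1100,1500(E),1200,1000,1600(E),1300,1000 - post-error trials
  # are 1200 and 1300
  log <- make_log(
    chosen = c("ball", "ball", "chair", "ball", "ball", "chair", "ball", "ball"),
    rt = c(1000, 1100, 1500, 1200, 1000, 1600, 1300, 1000),
    rating = "yes"
  )
  pe <- post_error_measures(log, gate = list(p_value = NA, method_used = "traditional"))
  expect_equal(pe$pes_ms, mean(c(1200, 1300)))
  expect_equal(pe$pcs_ms, mean(c(1100, 1500, 1000, 1600, 1000)))
  expect_equal(pe$pea, 1)           # both post-error trials correct
  expect_equal(pe$pca, 3 / 5)       # 1500 and 1600 are errors
  # robust variant: episodes (1100,1200) and (1000,1300)
  expect_equal(pe$robust_pes_ms, mean(c(1200 - 1100, 1300 - 1000)))
  # undetected errors here (rated "yes"); detected split empty
  expect_true(is.na(pe$pes_detected_ms))
  expect_equal(pe$pes_undetected_ms, pe$pes_ms)
})

test_that("post-trials that are timeouts drop from PES but zero PEA", {
  log <- make_log(
    chosen = c("ball", "chair", "ball", "chair", "ball", "ball"),
    timeout = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    rt = 1000, rating = "no"
  )
  # errors at trials 2 and 4; both post-trials (3 and 5) are timeouts
  pe <- post_error_measures(log, gate = list(p_value = NA, method_used = "traditional"))
  expect_true(is.na(pe$pes_ms))
  expect_equal(pe$pea, 0)
})

test_that("pairs spanning block breaks are excluded", {
  log <- make_log(
    block = c(1, 1, 2, 2),
    chosen = c("ball", "chair", "ball", "ball"),
    rt = c(900, 1400, 1111, 950), rating = "no"
  )
  pe <- post_error_measures(log, gate = list(p_value = NA, method_used = "traditional"))
  expect_true(is.na(pe$pes_ms))  # the only post-error pair crosses the break
  expect_equal(pe$pcs_ms, mean(c(1400, 950)))
})

test_that("vectorised measures equal naive per-definition oracles on random logs", {
  for (s in 1:100) {
    log <- random_log(n = 50, seed = s)
    rr <- response_rates(log)$overall
    o <- naive_rates(log)
    expect_equal(rr$correct_rate, o$correct_rate)
    expect_equal(rr$error_rate, o$error_rate)
    expect_equal(rr$timeout_rate, o$timeout_rate)
    expect_equal(rr$error_detection_rate, o$error_detection_rate)
    expect_equal(rr$correct_detection_rate, o$correct_detection_rate)
    expect_equal(rr$correct_rate + rr$error_rate + rr$timeout_rate, 1)

    pe <- post_error_measures(log, gate = list(p_value = NA, method_used = "traditional"))
    ope <- naive_post_error(log)
    expect_equal(pe$pes_ms, ope$pes)
    expect_equal(pe$pcs_ms, ope$pcs)
    expect_equal(pe$pea, ope$pea)
    expect_equal(pe$pca, ope$pca)
    expect_equal(pe$pes_detected_ms, ope$pes_detected)
    expect_equal(pe$pes_undetected_ms, ope$pes_undetected)
    expect_equal(pe$pea_detected, ope$pea_detected)
    expect_equal(pe$pea_undetected, ope$pea_undetected)
    expect_equal(pe$robust_pes_ms, ope$robust)

    es <- classify_error_sources(log)
    oes <- naive_error_sources(log)
    expect_equal(es$summary$n[es$summary$class == "rule2_misapplication"], oes$n_mis)
    expect_equal(es$summary$n[es$summary$class == "other"], oes$n_oth)
    expect_equal(es$misapplication_share, oes$share)
    expect_equal(es$summary$detection_rate[es$summary$class == "rule2_misapplication"],
                 oes$det_mis)

    # counting identity: detected + undetected + missing-rated = all errors
    err <- !log$is_timeout & !log$is_correct
    expect_equal(sum(err & is_detected(log$rating)) +
                   sum(err & is_undetected(log$rating)) +
                   sum(err & log$rating == "missing"), sum(err))
  }
})

test_that("error-source classification needs the extended schema", {
  log <- make_log(chosen = c("chair", "ball"), rating = "no")
  log$lure_target <- NA_character_
  expect_error(classify_error_sources(log), "lure_target")
})

test_that("inclusion criterion uses an inclusive >= 6 bound per error type", {
  mk <- function(n_det, n_undet) {
    make_log(chosen = rep("chair", n_det + n_undet),
             rating = c(rep("no", n_det), rep("yes", n_undet)))
  }
  expect_true(inclusion_check(mk(7, 7))$eligible)
  expect_false(inclusion_check(mk(10, 5))$eligible)
  expect_true(inclusion_check(mk(6, 6))$eligible)
  inc <- inclusion_check(mk(6, 6))
  expect_equal(inc$n_detected, 6)
  expect_equal(inc$n_undetected, 6)
})

test_that("post-timeout speeding recovers an injected speedup and a null", {
  cfg <- session_config(10, 32, seed = 31)
  fast <- agent_params(post_timeout_delta_ms = -200, pes_delta_ms = 0)
  log <- simulate_participant(cfg, fast, seed = 31)
  pts <- post_timeout_speeding(log)
  expect_lt(pts$difference_ms, 0)

  null_agent <- agent_params(post_timeout_delta_ms = 0, pes_delta_ms = 0,
                             learning_slope = 1)
  logs <- lapply(1:4, function(s) {
    cfg_s <- session_config(10, 32, seed = 40 + s)
    simulate_participant(cfg_s, null_agent, seed = 40 + s)
  })
  diffs <- vapply(logs, function(l) post_timeout_speeding(l)$difference_ms, numeric(1))
  ns <- vapply(logs, function(l) post_timeout_speeding(l)$n_post_timeout, numeric(1))
  pooled <- sum(diffs * ns) / sum(ns)
  # null agent: difference ~ 0 within a generous Monte-Carlo band
  expect_lt(abs(pooled), 100)
})

test_that("part specifications validate and contrast against the baseline", {
  expect_error(parse_parts("1-5,4-10"), "overlap")
  expect_error(parse_parts(list(1:5, 6:20), n_blocks = 15), "beyond")
  parts <- parse_parts("1-5,6-10,11-15")
  expect_equal(parts$part2, 6:10)

  # identical parts in expectation: same generative process in each part
  logs <- lapply(1:6, function(j) {
    cfg <- session_config(4, 32, seed = 50 + j)
    simulate_participant(cfg, agent_params(), seed = 50 + j,
                         participant_id = paste0("p", j))
  })
  pc <- part_contrasts(logs, list(1:2, 3:4))
  err_diff <- pc$contrasts$mean_diff[pc$contrasts$measure == "error_rate"]
  expect_lt(abs(err_diff), 0.1)
  expect_equal(nrow(pc$per_part), 12)

  # single participant: aggregates present, test statistics missing
  pc1 <- part_contrasts(logs[[1]], list(1:2, 3:4))
  expect_true(all(is.na(pc1$contrasts$t)))
  expect_equal(nrow(pc1$cohort_means), 2)
})
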