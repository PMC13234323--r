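# Generative behaviour of the synthetic participants.

toy_trial <- function(rule = 1, correct = "ball", lure = "bird") {
  list(required_rule = rule, correct_target = correct, lure_target = lure)
}

test_that("degenerate accuracy parameters are respected", {
  a <- agent_params(p_correct_rule1 = 1, p_correct_rule2 = 1)
  withr::with_seed(1, {
    for (k in 1:50) {
      r <- agent_respond(a, toy_trial(rule = sample(1:2, 1)))
      expect_equal(r$choice, "ball")
      expect_gt(r$rt_ms, 0)
    }
  })
})

test_that("rule-1 errors choose the lure at the misapplication rate", {
  a <- agent_params(p_correct_rule1 = 0, p_misapply = 0.76)
  n <- 10000
  withr::with_seed(2, {
    choices <- vapply(seq_len(n), function(i) {
      agent_respond(a, toy_trial())$choice
    }, character(1))
  })
  expect_false(any(choices == "ball"))  # never the correct target
  p_hat <- mean(choices == "bird")
  se <- sqrt(0.76 * 0.24 / n)
  expect_lt(abs(p_hat - 0.76), 3 * se)
  # non-lure errors are uniform over the remaining two wrong targets
  others <- choices[choices != "bird"]
  expect_gt(suppressWarnings(stats::chisq.test(table(others)))$p.value, 0.001)
})

test_that("error responses are slower than correct responses (log-normal mean oracle)", {
  a <- agent_params()
  n <- 4000
  withr::with_seed(3, {
    rt_ok <- replicate(n, agent_respond(agent_params(p_correct_rule1 = 1),
                                        toy_trial())$rt_ms)
    rt_err <- replicate(n, agent_respond(agent_params(p_correct_rule1 = 0),
                                         toy_trial())$rt_ms)
  })
  # arithmetic mean of lognormal(meanlog = log(mu) - s^2/2, s) is mu
  se_ok <- sd(rt_ok) / sqrt(n); se_err <- sd(rt_err) / sqrt(n)
  expect_lt(abs(mean(rt_ok) - a$rt_correct_mu_ms), 4 * se_ok)
  expect_lt(abs(mean(rt_err) - a$rt_error_mu_ms), 4 * se_err)
  expect_gt(mean(rt_err), mean(rt_ok))
})

test_that("learning scales RT down across blocks without touching accuracy", {
  a <- agent_params(learning_slope = 0.95, p_correct_rule1 = 0.8)
  withr::with_seed(4, {
    block_means <- vapply(c(1, 4, 8, 12), function(b) {
      mean(replicate(2000, agent_respond(a, toy_trial(), block_index = b)$rt_ms))
    }, numeric(1))
  })
  expect_true(all(diff(block_means) < 0))
  expect_equal(block_means[1] / block_means[4], 0.95^(-11), tolerance = 0.05)
})

test_that("ratings follow the kind-matched detection probabilities", {
  sure <- agent_params(p_detect_rule2 = 1, p_maybe = 0, p_rating_miss = 0)
  withr::with_seed(5, {
    r <- replicate(50, agent_evaluate(sure, list(type = "error", error_kind = "rule2")))
  })
  expect_true(all(r == "no"))

  miss <- agent_params(p_rating_miss = 1)
  withr::with_seed(6, {
    r <- replicate(50, agent_evaluate(miss, list(type = "correct")))
  })
  expect_true(all(r == "missing"))

  # among rated trials, detection is p_detect regardless of maybe-substitution
  a <- agent_params()
  n <- 10000
  withr::with_seed(7, {
    r <- replicate(n, agent_evaluate(a, list(type = "error", error_kind = "rule2")))
  })
  rated <- r[r != "missing"]
  p_hat <- mean(rated %in% c("no", "maybe_not"))
  p_exp <- a$p_detect_rule2
  expect_lt(abs(p_hat - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / length(rated)))
  expect_lt(abs(mean(r %in% c("maybe_yes", "maybe_not")) - a$p_maybe * (1 - a$p_rating_miss)),
            0.01)
})

test_that("timeout evaluations track the auto-chosen target's correctness", {
  a <- agent_params(timeout_eval_accuracy = 1, p_maybe = 0, p_rating_miss = 0)
  withr::with_seed(8, {
    r_good <- agent_evaluate(a, list(type = "timeout", auto_correct = TRUE))
    r_bad <- agent_evaluate(a, list(type = "timeout", auto_correct = FALSE))
  })
  expect_equal(r_good, "yes")
  expect_equal(r_bad, "no")
})

test_that("cohorts are reproducible, distinct, and centred on their anchors", {
  co1 <- default_cohort(21, seed = 10)
  co2 <- default_cohort(21, seed = 10)
  expect_identical(co1, co2)
  expect_length(unique(vapply(co1, function(a) a$p_detect_rule2, numeric(1))), 21)

  frozen <- default_cohort(3, seed = 10, sd_logit_accuracy = 0, sd_logit_detect = 0,
                           sd_logit_misapply = 0, sd_rt_mu_ms = 0)
  expect_identical(frozen[[1]], frozen[[2]])
  expect_equal(frozen[[1]]$p_detect_rule2, agent_params()$p_detect_rule2)

  # large-cohort mean of p_detect_rule2 matches the logit-normal expectation
  base <- agent_params()
  sd_l <- 0.7
  integrand <- function(z) plogis(qlogis(base$p_detect_rule2) + z) * stats::dnorm(z, 0, sd_l)
  mu_exact <- stats::integrate(integrand, -Inf, Inf)$value
  big <- default_cohort(500, seed = 11)
  vals <- vapply(big, function(a) a$p_detect_rule2, numeric(1))
  expect_lt(abs(mean(vals) - mu_exact), 3 * sd(vals) / sqrt(500))
})
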