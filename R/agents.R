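#' Parametric synthetic participant
#'
#' A generative stand-in for a human participant, parameterised so that the
#' simulated behaviour reproduces the statistical structure observed with
#' the paradigm: errors are slower than correct responses; rule-2 errors are
#' detected far more often than rule-1 errors; rule-1 errors are dominated
#' by lure choices (rule-2 misapplications, which are rarely detected); RTs
#' decline over blocks; responses slow slightly after errors and speed up
#' after timeouts.
#'
#' Default anchors (group means reported for the paradigm): correct-response
#' probabilities per rule around 0.8 (yielding roughly 73/18/9%
#' correct/error/timeout splits under the adaptive deadline), misapplication
#' share 0.76, detection probabilities 0.36 (misapplied rule-1 errors),
#' 0.89 (other rule-1 errors; the two mix to the observed 48.7% rule-1
#' detection), 0.87 (rule-2 errors), correct-confirmation 0.982, "maybe"
#' usage 4% of ratings, mean RTs 1400 ms (correct) and 1675 ms (error) with
#' log-normal trial noise.
#'
#' `freq_gain` models rule-1 practice: when rule 1 is required in more than
#' half of a block's trials, the log-odds of answering rule-1 trials
#' correctly increase by `freq_gain * (rule1_fraction - 0.5)`. This
#' one-sided gain reproduces the reported drop in error rate (with
#' detection unchanged) when rule 1 dominates, while leaving rule-2-heavy
#' blocks untouched (where the observed error rate is unchanged and only
#' detection rises, via the error mixture). Set `freq_gain = 0` for
#' frequency-invariant accuracy.
#'
#' @param p_correct_rule1,p_correct_rule2 Baseline probabilities of a
#'   correct response per required rule (before the frequency gain).
#' @param p_misapply Probability that a rule-1 error is the lure target
#'   (rule-2 misapplication); other rule-1 errors are uniform over the two
#'   remaining wrong targets.
#' @param rt_correct_mu_ms,rt_error_mu_ms Mean RT (ms) of correct/error
#'   responses in block 1; errors slower by default.
#' @param rt_sigma_log Log-scale SD of the log-normal RT noise.
#' @param learning_slope Per-block multiplicative RT factor (< 1 = faster
#'   with practice; accuracy does not drift).
#' @param pes_delta_ms Additive RT increment on trials directly following
#'   an error (post-error slowing signal; default 30 ms).
#' @param post_timeout_delta_ms Additive RT increment after a timeout
#'   (negative = post-timeout speeding; default -60 ms).
#' @param p_detect_rule1_lure,p_detect_rule1_other,p_detect_rule2
#'   Probabilities that an error of the given kind is rated "not correct".
#' @param p_confirm_correct Probability a correct response is rated
#'   "correct".
#' @param p_maybe Probability a rating uses its "maybe" variant.
#' @param p_rating_miss Probability of a missing rating.
#' @param timeout_eval_accuracy Probability of correctly evaluating the
#'   auto-chosen target of a timeout trial.
#' @param freq_gain One-sided rule-practice gain (log-odds per unit excess
#'   frequency above 0.5).
#' @return An object of class `sit_agent`.
#' @export
agent_params <- function(p_correct_rule1 = 0.84,
                         p_correct_rule2 = 0.80,
                         p_misapply = 0.76,
                         rt_correct_mu_ms = 1400,
                         rt_error_mu_ms = 1675,
                         rt_sigma_log = 0.25,
                         learning_slope = 0.99,
                         pes_delta_ms = 30,
                         post_timeout_delta_ms = -60,
                         p_detect_rule1_lure = 0.36,
                         p_detect_rule1_other = 0.89,
                         p_detect_rule2 = 0.87,
                         p_confirm_correct = 0.982,
                         p_maybe = 0.04,
                         p_rating_miss = 0.01,
                         timeout_eval_accuracy = 0.90,
                         freq_gain = 5) {
  a <- as.list(environment())
  probs <- c("p_correct_rule1", "p_correct_rule2", "p_misapply",
             "p_detect_rule1_lure", "p_detect_rule1_other", "p_detect_rule2",
             "p_confirm_correct", "p_maybe", "p_rating_miss",
             "timeout_eval_accuracy")
  for (nm in probs) {
    v <- a[[nm]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a probability in [0, 1].", call. = FALSE)
    }
  }
  stopifnot(a$rt_correct_mu_ms > 0, a$rt_error_mu_ms > 0,
            a$rt_sigma_log >= 0, a$learning_slope > 0)
  structure(a, class = "sit_agent")
}

# Effective per-rule accuracy given the block's planned rule-1 fraction.
# The practice gain applies to rule-1 trials only, and only when rule 1
# dominates: the paradigm's data show lower error rates when most trials
# demand rule 1, but an unchanged error rate when rule 2 dominates.
.effective_p_correct <- function(agent, rule, rule1_fraction) {
  base <- if (rule == 1) agent$p_correct_rule1 else agent$p_correct_rule2
  if (rule != 1 || agent$freq_gain == 0 || rule1_fraction <= 0.5) return(base)
  plogis(qlogis(base) + agent$freq_gain * (rule1_fraction - 0.5))
}

#' Draw one response from an agent
#'
#' Correctness is Bernoulli with the rule-matched (frequency-adjusted)
#' probability. On rule-1 errors the lure target is chosen with probability
#' `p_misapply`, otherwise one of the two remaining wrong targets uniformly;
#' rule-2 errors are uniform over the three wrong targets. RT is log-normal
#' with an arithmetic mean depending on correctness, scaled by
#' `learning_slope^(block_index - 1)` and shifted by the post-error /
#' post-timeout increments. The agent never converts its own slowness into
#' a timeout -- the engine races RT against the deadline.
#'
#' Uses the current RNG state.
#'
#' @param agent `sit_agent`.
#' @param trial One-row trial tibble (or list) with `required_rule`,
#'   `correct_target`, `lure_target`.
#' @param block_index 1-based block number.
#' @param prev Preceding-trial outcome: "none", "correct", "error",
#'   "timeout".
#' @param rule1_fraction Planned rule-1 fraction of the current block.
#' @param target_set `sit_target_set` (supplies the four categories).
#' @return `list(choice, rt_ms)`.
#' @export
agent_respond <- function(agent, trial, block_index = 1, prev = "none",
                          rule1_fraction = 0.5,
                          target_set = build_target_set(0)) {
  rule <- trial$required_rule
  p_ok <- .effective_p_correct(agent, rule, rule1_fraction)
  ok <- runif(1) < p_ok
  if (ok) {
    choice <- trial$correct_target
  } else if (rule == 1 && runif(1) < agent$p_misapply) {
    choice <- trial$lure_target
  } else {
    wrong <- setdiff(target_set$categories, trial$correct_target)
    if (rule == 1) wrong <- setdiff(wrong, trial$lure_target)
    choice <- wrong[sample.int(length(wrong), 1)]
  }
  mu <- (if (ok) agent$rt_correct_mu_ms else agent$rt_error_mu_ms) *
    agent$learning_slope^(block_index - 1)
  meanlog <- log(mu) - agent$rt_sigma_log^2 / 2  # arithmetic mean = mu
  rt <- rlnorm(1, meanlog, agent$rt_sigma_log)
  if (prev == "error") rt <- rt + agent$pes_delta_ms
  if (prev == "timeout") rt <- rt + agent$post_timeout_delta_ms
  list(choice = choice, rt_ms = max(rt, 150))
}

#' Draw one evaluation rating from an agent
#'
#' Ratings are Bernoulli detections with the outcome-kind-matched
#' probability (error kinds: lure vs other rule-1 errors, rule-2 errors;
#' correct responses confirmed with `p_confirm_correct`; timeout
#' auto-targets evaluated correctly with `timeout_eval_accuracy`), then a
#' "maybe" variant is substituted with probability `p_maybe`, and the whole
#' rating goes missing with probability `p_rating_miss`.
#'
#' @param agent `sit_agent`.
#' @param outcome Outcome list as passed by [run_session()]: fields `type`,
#'   `error_kind`, `auto_correct`.
#' @return One of `"yes"`, `"maybe_yes"`, `"maybe_not"`, `"no"`,
#'   `"missing"`.
#' @export
agent_evaluate <- function(agent, outcome) {
  if (runif(1) < agent$p_rating_miss) return("missing")
  says_correct <- switch(
    outcome$type,
    correct = runif(1) < agent$p_confirm_correct,
    error = {
      p_detect <- switch(outcome$error_kind,
                         rule1_lure = agent$p_detect_rule1_lure,
                         rule1_other = agent$p_detect_rule1_other,
                         rule2 = agent$p_detect_rule2)
      !(runif(1) < p_detect)
    },
    timeout = {
      judged_right <- runif(1) < agent$timeout_eval_accuracy
      if (judged_right) outcome$auto_correct else !outcome$auto_correct
    },
    stop("Unknown outcome type '", outcome$type, "'.", call. = FALSE)
  )
  maybe <- runif(1) < agent$p_maybe
  if (says_correct) {
    if (maybe) "maybe_yes" else "yes"
  } else {
    if (maybe) "maybe_not" else "no"
  }
}

#' Wrap agent parameters into an engine responder
#'
#' @param agent `sit_agent`.
#' @param config The session's `sit_config` (supplies each block's planned
#'   rule-1 fraction for the practice gain and the counterbalancing).
#' @return A responder list with `respond` and `evaluate`, see
#'   [run_session()].
#' @export
make_responder <- function(agent, config) {
  stopifnot(inherits(agent, "sit_agent"), inherits(config, "sit_config"))
  target_set <- build_target_set(config$counterbalance_id)
  list(
    respond = function(trial, threshold_ms, block_index, prev) {
      agent_respond(agent, trial, block_index, prev,
                    rule1_fraction = config$rule1_fraction[block_index],
                    target_set = target_set)
    },
    evaluate = function(outcome) agent_evaluate(agent, outcome)
  )
}

#' Draw a cohort of synthetic participants
#'
#' Per-agent parameters are jittered around the default anchors so that
#' between-agent spread resembles the between-subject standard deviations
#' reported for the paradigm (error rate SD around 5-6 percentage points,
#' detection-rate SDs around 15 points, RT SDs around 120 ms).
#' Probabilities are jittered on the log-odds scale; RT means additively.
#'
#' @param n_agents Number of agents.
#' @param seed Seed for the cohort draw.
#' @param base `sit_agent` centre of the cohort.
#' @param sd_logit_accuracy,sd_logit_detect,sd_logit_misapply Log-odds SDs.
#' @param sd_rt_mu_ms SD (ms) of the shared RT-mean shift.
#' @return List of `sit_agent` objects (length `n_agents`).
#' @export
default_cohort <- function(n_agents, seed = 1, base = agent_params(),
                           sd_logit_accuracy = 0.35,
                           sd_logit_detect = 0.7,
                           sd_logit_misapply = 0.5,
                           sd_rt_mu_ms = 120) {
  stopifnot(n_agents >= 1)
  jit <- function(p, sd) plogis(qlogis(p) + rnorm(1, 0, sd))
  withr::with_seed(seed, {
    lapply(seq_len(n_agents), function(i) {
      rt_shift <- rnorm(1, 0, sd_rt_mu_ms)
      a <- base
      a$p_correct_rule1 <- jit(base$p_correct_rule1, sd_logit_accuracy)
      a$p_correct_rule2 <- jit(base$p_correct_rule2, sd_logit_accuracy)
      a$p_misapply <- jit(base$p_misapply, sd_logit_misapply)
      a$p_detect_rule1_lure <- jit(base$p_detect_rule1_lure, sd_logit_detect)
      a$p_detect_rule1_other <- jit(base$p_detect_rule1_other, sd_logit_detect)
      a$p_detect_rule2 <- jit(base$p_detect_rule2, sd_logit_detect)
      a$p_confirm_correct <- jit(base$p_confirm_correct, sd_logit_detect)
      a$rt_correct_mu_ms <- base$rt_correct_mu_ms + rt_shift
      a$rt_error_mu_ms <- base$rt_error_mu_ms + rt_shift
      a
    })
  })
}
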