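#' Engine parameters
#'
#' Timing, adaptive-deadline and scoring constants of the task. The
#' defaults are the published paradigm's values: the timeout threshold
#' starts at 2000 ms and is adjusted after every 16 trials (twice per
#' 32-trial block) -- raised by 10% when windowed accuracy falls below 60%,
#' lowered by 10% when it exceeds 90%, unchanged in between (boundary
#' accuracies count as inside the band). Correct responses earn 10 points;
#' correct self-evaluations earn a further 3 points, also on timeout trials.
#'
#' `threshold_floor_ms` has no published counterpart; it is a safety clamp
#' preventing a degenerate all-timeout session with very fast responders.
#'
#' @param threshold_start_ms Initial timeout threshold (ms).
#' @param window_len Trials per adaptive accuracy window.
#' @param acc_low,acc_high Accuracy band limits (strict inequalities).
#' @param step_frac Relative threshold step (0.10 = 10%).
#' @param threshold_floor_ms Lower clamp for the threshold (ms).
#' @param rating_deadline_ms Evaluation-screen deadline (ms).
#' @param highlight_ms Chosen-target highlight duration (ms).
#' @param blank_ms Blank screen before the rating (ms).
#' @param iti_range_ms Two-element range of the inter-trial interval (ms).
#' @param points_correct Points for a correct self-made response.
#' @param points_eval Points for a correct evaluation.
#' @return An object of class `sit_engine_params`.
#' @export
engine_params <- function(threshold_start_ms = 2000,
                          window_len = 16L,
                          acc_low = 0.60,
                          acc_high = 0.90,
                          step_frac = 0.10,
                          threshold_floor_ms = 300,
                          rating_deadline_ms = 4000,
                          highlight_ms = 700,
                          blank_ms = 1000,
                          iti_range_ms = c(600, 1000),
                          points_correct = 10L,
                          points_eval = 3L) {
  p <- list(threshold_start_ms = threshold_start_ms,
            window_len = as.integer(window_len),
            acc_low = acc_low, acc_high = acc_high,
            step_frac = step_frac,
            threshold_floor_ms = threshold_floor_ms,
            rating_deadline_ms = rating_deadline_ms,
            highlight_ms = highlight_ms, blank_ms = blank_ms,
            iti_range_ms = iti_range_ms,
            points_correct = as.integer(points_correct),
            points_eval = as.integer(points_eval))
  stopifnot(p$acc_low < p$acc_high, p$step_frac > 0, p$step_frac < 1,
            p$threshold_floor_ms < p$threshold_start_ms,
            p$window_len >= 1, length(p$iti_range_ms) == 2,
            p$iti_range_ms[1] <= p$iti_range_ms[2])
  structure(p, class = "sit_engine_params")
}

#' Adaptive threshold update
#'
#' Applies the windowed-accuracy rule to the current timeout threshold:
#' accuracy below `acc_low` raises the threshold by `step_frac`, accuracy
#' above `acc_high` lowers it by `step_frac` (clamped at the floor), and
#' accuracy inside the closed band leaves it unchanged. Timeout trials count
#' as not correct.
#'
#' @param window_correct Logical vector of the last `window_len` trial
#'   outcomes (`TRUE` = self-made correct response).
#' @param threshold_ms Current threshold.
#' @param params `sit_engine_params`.
#' @return The new threshold (ms).
#' @examples
#' update_threshold(rep(c(TRUE, FALSE), 8), 2000, engine_params())  # 0.50 -> 2200
#' @export
update_threshold <- function(window_correct, threshold_ms, params = engine_params()) {
  if (length(window_correct) != params$window_len) {
    stop("`window_correct` must contain exactly ", params$window_len,
         " outcomes.", call. = FALSE)
  }
  acc <- mean(window_correct)
  if (acc < params$acc_low) {
    threshold_ms * (1 + params$step_frac)
  } else if (acc > params$acc_high) {
    max(threshold_ms * (1 - params$step_frac), params$threshold_floor_ms)
  } else {
    threshold_ms
  }
}

#' Balanced timeout-target pool
#'
#' On a timeout the software displays a randomly chosen target. To keep the
#' displayed targets balanced, draws come without replacement from a pool
#' holding each target twice; when the pool is exhausted it is refilled and
#' the drawing starts anew.
#'
#' `new_timeout_pool()` returns a stateful pool; `$draw()` consumes the
#' current RNG stream.
#'
#' @param categories The four target categories.
#' @return An environment with `draw()` (returns a category) and
#'   `remaining()` (current pool contents).
#' @examples
#' set.seed(1)
#' pool <- new_timeout_pool()
#' table(replicate(8, pool$draw()))  # each target exactly twice
#' @export
new_timeout_pool <- function(categories = .sit_categories) {
  pool <- character(0)
  draw <- function() {
    if (length(pool) == 0) pool <<- rep(categories, 2)
    i <- sample.int(length(pool), 1)
    out <- pool[i]
    pool <<- pool[-i]
    out
  }
  remaining <- function() pool
  env <- new.env(parent = emptyenv())
  env$draw <- draw
  env$remaining <- remaining
  env
}

#' Score a finalized trial
#'
#' A self-made correct response earns `points_correct`; a correct
#' evaluation earns `points_eval` regardless of expressed certainty
#' ("maybe" variants score identically). Timeout trials earn no main-task
#' points but the evaluation of the auto-chosen target still counts, so 3
#' points remain attainable. A missing rating earns no evaluation points.
#'
#' @param is_timeout,is_correct Trial outcome flags (`is_correct` refers to
#'   the auto-chosen target on timeout trials).
#' @param eval_correct Logical or `NA` (missing rating).
#' @param params `sit_engine_params`.
#' @return Integer points earned.
#' @export
score_trial <- function(is_timeout, is_correct, eval_correct, params = engine_params()) {
  pts <- 0L
  if (!is_timeout && is_correct) pts <- pts + params$points_correct
  if (!is.na(eval_correct) && eval_correct) pts <- pts + params$points_eval
  pts
}

#' Run a session against a responder
#'
#' Simulates the full trial loop on a virtual clock: inter-trial interval,
#' response versus threshold race (a response time at or above the deadline
#' becomes a timeout with a pool-drawn auto-target), highlight and blank
#' delays, the evaluation rating with its own deadline, scoring, and the
#' adaptive threshold update after every `window_len` trials.
#'
#' A responder is a list with two functions:
#' * `respond(trial, threshold_ms, block_index, prev)` returning
#'   `list(choice = <category>, rt_ms = <numeric>)`; `prev` is the outcome
#'   type of the preceding trial in the same block
#'   (`"none"`, `"correct"`, `"error"`, `"timeout"`).
#' * `evaluate(outcome)` returning one of
#'   `"yes"`, `"maybe_yes"`, `"maybe_not"`, `"no"`, `"missing"`; `outcome`
#'   is a list with `type` (`"correct"`, `"error"`, `"timeout"`),
#'   `error_kind` (`"rule1_lure"`, `"rule1_other"`, `"rule2"` or `NA`) and
#'   `auto_correct` (timeout trials).
#'
#' @param plan A `sit_plan`.
#' @param responder A responder, e.g. [make_responder()].
#' @param params Engine parameters; defaults to the plan's configured ones.
#' @param seed Seed for the engine's randomness (ITI, pool, responder draws
#'   share one stream), defaulting to the plan seed.
#' @param participant_id,session_id Identifiers copied into the log.
#' @return A trial-log tibble (one row per trial, see [trial_log_columns()])
#'   with attributes `score`, `max_score` and `block_summary` (per-block
#'   score table shown at the break screens).
#' @export
run_session <- function(plan, responder, params = NULL, seed = NULL,
                        participant_id = "sim-01", session_id = "s1") {
  stopifnot(inherits(plan, "sit_plan"),
            is.list(responder), is.function(responder$respond),
            is.function(responder$evaluate))
  params <- params %||% plan$config$engine
  seed <- seed %||% plan$config$seed
  trials <- plan$trials
  n <- nrow(trials)
  categories <- plan$target_set$categories

  chosen <- character(n); rt <- rep(NA_real_, n)
  is_timeout <- logical(n); is_correct <- logical(n)
  rating <- character(n); eval_correct <- rep(NA, n)
  thr_at <- numeric(n); pts <- integer(n)
  iti <- numeric(n); onset <- numeric(n)

  # Column vectors once, lightweight per-trial lists in the loop: a tibble
  # row extraction per trial dominates runtime otherwise.
  v_block <- trials$block_index
  v_rule <- trials$required_rule
  v_correct <- trials$correct_target
  v_lure <- trials$lure_target
  v_global <- trials$global_trial_index

  withr::with_seed(seed, {
    pool <- new_timeout_pool(categories)
    threshold <- params$threshold_start_ms
    window <- logical(0)
    clock <- 0
    prev <- "none"
    prev_block <- 0L

    for (i in seq_len(n)) {
      tr <- list(block_index = v_block[i], required_rule = v_rule[i],
                 correct_target = v_correct[i], lure_target = v_lure[i],
                 global_trial_index = v_global[i])
      if (tr$block_index != prev_block) {
        prev <- "none"           # block breaks reset trial-to-trial carry-over
        prev_block <- tr$block_index
      }
      thr_at[i] <- threshold
      iti[i] <- runif(1, params$iti_range_ms[1], params$iti_range_ms[2])
      onset[i] <- clock + iti[i]

      resp <- responder$respond(tr, threshold, tr$block_index, prev)
      if (!is.numeric(resp$rt_ms) || is.na(resp$rt_ms)) {
        stop("Responder returned an invalid rt_ms on trial ", i, ".", call. = FALSE)
      }
      if (resp$rt_ms >= threshold) {
        is_timeout[i] <- TRUE
        chosen[i] <- pool$draw()
        rt[i] <- NA_real_
        elapsed <- threshold
      } else {
        if (!resp$choice %in% categories) {
          stop("Responder chose an unknown target '", resp$choice,
               "' on trial ", i, ".", call. = FALSE)
        }
        chosen[i] <- resp$choice
        rt[i] <- resp$rt_ms
        elapsed <- resp$rt_ms
      }
      is_correct[i] <- chosen[i] == tr$correct_target

      outcome <- list(
        type = if (is_timeout[i]) "timeout"
               else if (is_correct[i]) "correct" else "error",
        error_kind = if (!is_timeout[i] && !is_correct[i]) {
          if (tr$required_rule == 1) {
            if (chosen[i] == tr$lure_target) "rule1_lure" else "rule1_other"
          } else "rule2"
        } else NA_character_,
        auto_correct = if (is_timeout[i]) is_correct[i] else NA,
        required_rule = tr$required_rule
      )
      rating[i] <- responder$evaluate(outcome)
      if (!rating[i] %in% .sit_ratings) {
        stop("Responder returned an invalid rating '", rating[i], "'.", call. = FALSE)
      }
      eval_correct[i] <- if (rating[i] == "missing") NA else {
        (rating[i] %in% c("yes", "maybe_yes")) == is_correct[i]
      }
      pts[i] <- score_trial(is_timeout[i], is_correct[i], eval_correct[i], params)

      rating_dur <- if (rating[i] == "missing") params$rating_deadline_ms else
        min(runif(1, 500, 1500), params$rating_deadline_ms)
      clock <- onset[i] + elapsed + params$highlight_ms + params$blank_ms + rating_dur

      window <- c(window, !is_timeout[i] && is_correct[i])
      if (length(window) == params$window_len) {
        threshold <- update_threshold(window, threshold, params)
        window <- logical(0)
      }
      prev <- outcome$type
    }
  })

  log <- tibble::tibble(
    participant_id = participant_id,
    session_id = session_id,
    trials[, c("block_index", "trial_index_in_block", "global_trial_index",
               "required_rule", "correct_target", "lure_target",
               "item1_category", "item1_colour", "item1_exemplar",
               "item1_scale", "item1_tilt",
               "item2_category", "item2_colour", "item2_exemplar",
               "item2_scale", "item2_tilt")],
    chosen_target = chosen,
    rt_ms = rt,
    is_timeout = is_timeout,
    is_correct = is_correct,
    rating = rating,
    eval_correct = eval_correct,
    threshold_at_trial_ms = thr_at,
    points_earned = pts,
    iti_ms = iti,
    clock_onset_ms = onset
  )
  blk <- dplyr::summarise(
    dplyr::group_by(log, .data$block_index),
    score = sum(.data$points_earned),
    max_score = dplyr::n() * (params$points_correct + params$points_eval),
    .groups = "drop"
  )
  blk$cum_score <- cumsum(blk$score)
  blk$cum_max_score <- cumsum(blk$max_score)
  attr(log, "score") <- sum(pts)
  attr(log, "max_score") <- n * (params$points_correct + params$points_eval)
  attr(log, "block_summary") <- blk
  log
}

#' Simulate one synthetic participant end to end
#'
#' Convenience wrapper: builds the session plan for `config` and runs it
#' with a responder derived from `agent`.
#'
#' @param config A `sit_config`.
#' @param agent `sit_agent` parameters, see [agent_params()].
#' @param seed Seed for the run (plan seed comes from `config`).
#' @param participant_id Identifier written into the log.
#' @return A trial-log tibble, see [run_session()].
#' @export
simulate_participant <- function(config, agent = agent_params(),
                                 seed = config$seed, participant_id = "sim-01") {
  plan <- build_session(config)
  run_session(plan, make_responder(agent, config), seed = seed,
              participant_id = participant_id)
}

#' Simulate a cohort of synthetic participants
#'
#' @param config A `sit_config` shared by all participants.
#' @param agents List of `sit_agent` parameter sets (e.g. [default_cohort()]).
#' @param seed Base seed; participant j runs with `seed + j` and a plan
#'   built from `config$seed + 1000 * j` so trial orders differ.
#' @return A list of trial-log tibbles, one per agent.
#' @export
simulate_cohort <- function(config, agents, seed = 1) {
  stopifnot(length(agents) >= 1)
  lapply(seq_along(agents), function(j) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + 1000L * j)
    sim <- simulate_participant(cfg, agents[[j]], seed = seed + j,
                                participant_id = sprintf("sim-%02d", j))
    sim
  })
}
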