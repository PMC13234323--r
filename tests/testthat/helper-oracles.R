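# Naive, per-definition reimplementations used as independent oracles, plus
# programmatic log fixtures. These deliberately use plain loops and direct
# counting, not the package's vectorised code paths.

fig1_targets <- function() build_target_set(0)

# Minimal hand-specified log: defaults give a valid schema row per trial.
make_log <- function(block = 1L, rule = 1L, correct = "ball", lure = "bird",
                     chosen = correct, rt = 1000, timeout = FALSE,
                     rating = "yes") {
  n <- max(lengths(list(block, rule, correct, lure, chosen, rt, timeout, rating)))
  rec <- function(x) rep_len(x, n)
  block <- rec(block); rule <- rec(rule); correct <- rec(correct)
  lure <- rec(lure); chosen <- rec(chosen); rt <- rec(rt)
  timeout <- rec(timeout); rating <- rec(rating)
  rt[timeout] <- NA_real_
  is_correct <- chosen == correct
  eval_correct <- ifelse(rating == "missing", NA,
                         (rating %in% c("yes", "maybe_yes")) == is_correct)
  tibble::tibble(
    participant_id = "toy", session_id = "s1",
    block_index = as.integer(block),
    trial_index_in_block = stats::ave(seq_len(n), block, FUN = seq_along),
    global_trial_index = seq_len(n),
    required_rule = as.integer(rule),
    correct_target = correct, lure_target = lure,
    item1_category = "chair", item1_colour = "green",
    item1_exemplar = 1L, item1_scale = 0.8, item1_tilt = 0,
    item2_category = "bird", item2_colour = "red",
    item2_exemplar = 1L, item2_scale = 0.8, item2_tilt = 0,
    chosen_target = chosen, rt_ms = rt,
    is_timeout = timeout, is_correct = is_correct,
    rating = rating, eval_correct = eval_correct,
    threshold_at_trial_ms = 2000, points_earned = 0L,
    iti_ms = 800, clock_onset_ms = seq_len(n) * 4000
  )
}

# Random schema-valid log for oracle-equivalence sweeps.
random_log <- function(n = 50, seed = 1, n_blocks = 2) {
  withr::with_seed(seed, {
    cats <- c("ball", "ice_cream", "chair", "bird")
    rule <- sample(1:2, n, replace = TRUE)
    correct <- sample(cats, n, replace = TRUE)
    lure <- vapply(seq_len(n), function(i) {
      if (rule[i] == 2) correct[i] else sample(setdiff(cats, correct[i]), 1)
    }, character(1))
    timeout <- runif(n) < 0.12
    chosen <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.6) correct[i] else sample(cats, 1)
    }, character(1))
    rt <- ifelse(timeout, NA_real_, runif(n, 600, 2200))
    rating <- sample(c("yes", "maybe_yes", "maybe_not", "no", "missing"),
                     n, replace = TRUE, prob = c(0.5, 0.05, 0.05, 0.3, 0.1))
    log <- make_log(block = rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[1:n],
                    rule = rule, correct = correct, lure = lure,
                    chosen = chosen, rt = rt, timeout = timeout, rating = rating)
    log
  })
}

is_detected <- function(r) r %in% c("no", "maybe_not")
is_undetected <- function(r) r %in% c("yes", "maybe_yes")

# Oracle 1: response/detection rates by direct counting.
naive_rates <- function(log) {
  n <- nrow(log)
  nc <- ne <- nt <- det <- rated_err <- conf <- rated_cor <- 0
  for (i in seq_len(n)) {
    if (log$is_timeout[i]) {
      nt <- nt + 1
    } else if (log$is_correct[i]) {
      nc <- nc + 1
      if (log$rating[i] != "missing") {
        rated_cor <- rated_cor + 1
        if (is_undetected(log$rating[i])) conf <- conf + 1
      }
    } else {
      ne <- ne + 1
      if (log$rating[i] != "missing") {
        rated_err <- rated_err + 1
        if (is_detected(log$rating[i])) det <- det + 1
      }
    }
  }
  list(correct_rate = nc / n, error_rate = ne / n, timeout_rate = nt / n,
       error_detection_rate = if (rated_err > 0) det / rated_err else NA_real_,
       correct_detection_rate = if (rated_cor > 0) conf / rated_cor else NA_real_)
}

# Oracle 2: post-error/post-correct measures by explicit pair loops.
naive_post_error <- function(log) {
  log <- log[order(log$global_trial_index), ]
  n <- nrow(log)
  pes <- pcs <- pea <- pca <- pes_d <- pes_u <- pea_d <- pea_u <- c()
  for (i in 2:n) {
    if (log$block_index[i] != log$block_index[i - 1]) next
    if (log$global_trial_index[i] != log$global_trial_index[i - 1] + 1) next
    prev_err <- !log$is_timeout[i - 1] && !log$is_correct[i - 1]
    prev_cor <- !log$is_timeout[i - 1] && log$is_correct[i - 1]
    post_correct <- !log$is_timeout[i] && log$is_correct[i]
    if (prev_err) {
      pea <- c(pea, post_correct)
      if (is_detected(log$rating[i - 1])) pea_d <- c(pea_d, post_correct)
      if (is_undetected(log$rating[i - 1])) pea_u <- c(pea_u, post_correct)
      if (!log$is_timeout[i]) {
        pes <- c(pes, log$rt_ms[i])
        if (is_detected(log$rating[i - 1])) pes_d <- c(pes_d, log$rt_ms[i])
        if (is_undetected(log$rating[i - 1])) pes_u <- c(pes_u, log$rt_ms[i])
      }
    }
    if (prev_cor) {
      pca <- c(pca, post_correct)
      if (!log$is_timeout[i]) pcs <- c(pcs, log$rt_ms[i])
    }
  }
  rob <- c()
  for (i in 2:(n - 1)) {
    if (!(!log$is_timeout[i] && !log$is_correct[i])) next
    same <- log$block_index[i - 1] == log$block_index[i] &&
      log$block_index[i + 1] == log$block_index[i] &&
      log$global_trial_index[i] - log$global_trial_index[i - 1] == 1 &&
      log$global_trial_index[i + 1] - log$global_trial_index[i] == 1
    if (same && !log$is_timeout[i - 1] && !log$is_timeout[i + 1]) {
      rob <- c(rob, log$rt_ms[i + 1] - log$rt_ms[i - 1])
    }
  }
  m <- function(x) if (length(x)) mean(x) else NA_real_
  list(pes = m(pes), pcs = m(pcs), pea = m(pea), pca = m(pca),
       pes_detected = m(pes_d), pes_undetected = m(pes_u),
       pea_detected = m(pea_d), pea_undetected = m(pea_u), robust = m(rob))
}

# Oracle 3: rule-1 error-source classification by direct looping.
naive_error_sources <- function(log) {
  n_mis <- n_oth <- det_mis <- rated_mis <- 0
  for (i in seq_len(nrow(log))) {
    if (log$required_rule[i] != 1 || log$is_timeout[i] || log$is_correct[i]) next
    if (log$chosen_target[i] == log$lure_target[i]) {
      n_mis <- n_mis + 1
      if (log$rating[i] != "missing") {
        rated_mis <- rated_mis + 1
        if (is_detected(log$rating[i])) det_mis <- det_mis + 1
      }
    } else {
      n_oth <- n_oth + 1
    }
  }
  list(n_mis = n_mis, n_oth = n_oth,
       share = if (n_mis + n_oth > 0) n_mis / (n_mis + n_oth) else NA_real_,
       det_mis = if (rated_mis > 0) det_mis / rated_mis else NA_real_)
}

# Oracle 4: rule semantics by direct definition (independent of
# classify_stimulus internals).
naive_classify <- function(c1, k1, c2, k2, ts) {
  matched <- character(0)
  absent <- character(0)
  for (tc in ts$categories) {
    col <- ts$colour_of[[tc]]
    if ((c1 == tc && k1 == col) || (c2 == tc && k2 == col)) {
      matched <- c(matched, tc)
    }
    if (tc != c1 && tc != c2 && col != k1 && col != k2) absent <- c(absent, tc)
  }
  if (length(absent) != 1) return(list(ok = FALSE, reason = "no_unique_lure"))
  if (length(matched) > 1) return(list(ok = FALSE, reason = "multiple_matches"))
  if (length(matched) == 1) {
    list(ok = TRUE, rule = 1L, correct = matched, lure = absent)
  } else {
    list(ok = TRUE, rule = 2L, correct = absent, lure = absent)
  }
}

# Simple scripted responders for engine tests.
perfect_responder <- function() {
  list(respond = function(trial, threshold_ms, block_index, prev) {
    list(choice = trial$correct_target, rt_ms = 200)
  },
  evaluate = function(outcome) if (outcome$type == "correct") "yes" else "no")
}

never_responder <- function() {
  list(respond = function(trial, threshold_ms, block_index, prev) {
    list(choice = trial$correct_target, rt_ms = 1e9)
  },
  evaluate = function(outcome) "no")
}

coin_responder <- function() {
  # Instant responses, exactly 50% correct by alternation.
  flip <- TRUE
  list(respond = function(trial, threshold_ms, block_index, prev) {
    flip <<- !flip
    cats <- c("ball", "ice_cream", "chair", "bird")
    choice <- if (flip) trial$correct_target else
      setdiff(cats, trial$correct_target)[1]
    list(choice = choice, rt_ms = 200)
  },
  evaluate = function(outcome) "yes")
}
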