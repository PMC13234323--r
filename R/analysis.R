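# Behavioural-analysis suite for trial logs.
#
# All functions take a trial-log tibble (see trial_log_columns()). The
# analysis conventions throughout:
#   * "error" and "correct" refer to self-made responses; timeouts are a
#     third response type.
#   * detected   = rated "no" or "maybe_not"
#     undetected = rated "yes" or "maybe_yes"
#     (the rare "maybe" variants are collapsed at analysis time; raw
#     4-level ratings stay in the log). Missing ratings are excluded from
#     every detection denominator.
#   * empty denominators yield NA, never 0.

.detected <- function(rating) rating %in% c("no", "maybe_not")
.undetected <- function(rating) rating %in% c("yes", "maybe_yes")
.rated <- function(rating) rating != "missing"

.rate_row <- function(log) {
  n <- nrow(log)
  err <- !log$is_timeout & !log$is_correct
  cor <- !log$is_timeout & log$is_correct
  rated_err <- err & .rated(log$rating)
  rated_cor <- cor & .rated(log$rating)
  tibble::tibble(
    n_trials = n,
    correct_rate = sum(cor) / n,
    error_rate = sum(err) / n,
    timeout_rate = sum(log$is_timeout) / n,
    error_detection_rate = if (any(rated_err)) {
      sum(.detected(log$rating) & err) / sum(rated_err)
    } else NA_real_,
    correct_detection_rate = if (any(rated_cor)) {
      sum(.undetected(log$rating) & cor) / sum(rated_cor)
    } else NA_real_
  )
}

#' Response and detection rates
#'
#' Computes the proportion of all trials answered correctly, incorrectly,
#' or aborted by a timeout, together with the error detection rate
#' (detected errors / all rated errors) and the correct detection rate
#' (confirmed correct responses / all rated correct responses) -- overall,
#' per block, and optionally per part.
#'
#' @param log A trial-log tibble.
#' @param parts Optional part specification (see [parse_parts()]): a list
#'   of block-index vectors, or a string like `"1-5,6-10,11-15"`.
#' @return An object of class `sit_rates`: list with tibbles `overall`
#'   (one row), `by_block`, and `by_part` (`NULL` unless `parts` given).
#' @export
response_rates <- function(log, parts = NULL) {
  .check_log(log)
  by_block <- dplyr::bind_rows(lapply(split(log, log$block_index), .rate_row))
  by_block <- dplyr::bind_cols(
    tibble::tibble(block_index = sort(unique(log$block_index))), by_block
  )
  by_part <- NULL
  if (!is.null(parts)) {
    parts <- parse_parts(parts, max(log$block_index))
    by_part <- dplyr::bind_rows(lapply(seq_along(parts), function(p) {
      dplyr::bind_cols(tibble::tibble(part = p),
                       .rate_row(log[log$block_index %in% parts[[p]], ]))
    }))
  }
  structure(list(overall = .rate_row(log), by_block = by_block, by_part = by_part),
            class = "sit_rates")
}

#' @export
print.sit_rates <- function(x, ...) {
  cat("<sit_rates>\n")
  print(x$overall)
  invisible(x)
}

#' Rule-wise error counts and detection rates
#'
#' Splits errors by the rule the trial required: error counts, each rule's
#' share of all errors, the error rate among that rule's trials, and the
#' detection rates within rule.
#'
#' @param log A trial-log tibble.
#' @return A tibble with one row per rule (1 and 2; rules absent from the
#'   log get NA cells).
#' @export
split_by_rule <- function(log) {
  .check_log(log)
  err_all <- sum(!log$is_timeout & !log$is_correct)
  rows <- lapply(c(1L, 2L), function(r) {
    sub <- log[log$required_rule == r, ]
    if (nrow(sub) == 0) {
      return(tibble::tibble(rule = r, n_trials = 0L, n_errors = NA_integer_,
                            error_rate = NA_real_, error_share = NA_real_,
                            detection_rate = NA_real_,
                            correct_detection_rate = NA_real_))
    }
    rr <- .rate_row(sub)
    n_err <- as.integer(round(rr$error_rate * rr$n_trials))
    tibble::tibble(
      rule = r, n_trials = rr$n_trials, n_errors = n_err,
      error_rate = rr$error_rate,
      error_share = if (err_all > 0) n_err / err_all else NA_real_,
      detection_rate = rr$error_detection_rate,
      correct_detection_rate = rr$correct_detection_rate
    )
  })
  dplyr::bind_rows(rows)
}

# Eligible (prev, post) pairs: consecutive global trials within one block.
.post_pairs <- function(log) {
  ord <- order(log$global_trial_index)
  log <- log[ord, ]
  n <- nrow(log)
  if (n < 2) return(NULL)
  prev <- log[-n, ]
  post <- log[-1, ]
  keep <- prev$block_index == post$block_index &
    post$global_trial_index == prev$global_trial_index + 1
  list(prev = prev[keep, ], post = post[keep, ])
}

.prev_type <- function(prev) {
  ifelse(prev$is_timeout, "timeout", ifelse(prev$is_correct, "correct", "error"))
}

#' Post-error slowing, accuracy, and their splits
#'
#' Traditional post-error slowing (PES) is the mean RT of trials that
#' directly follow an error; post-correct slowing (PCS) is the mean RT of
#' trials following a correct response. Post-trials that are themselves
#' timeouts are excluded from the RT means (they have no RT) but count as
#' not correct in the accuracy measures (post-error accuracy PEA /
#' post-correct accuracy PCA). Pairs spanning block breaks are excluded.
#' PES and PEA are additionally split by whether the preceding error was
#' detected.
#'
#' The robust variant is the matched pre/post difference: for error
#' episodes whose flanking trials (one before, one after, same block) both
#' carry an RT, the mean of (post-error RT - pre-error RT).
#'
#' `method_used` reports which PES estimator the stationarity gate selects
#' (`"traditional"` when the RT series is stationary, `"robust"`
#' otherwise); both estimates are always returned.
#'
#' @param log A trial-log tibble.
#' @param gate Optional result of [adf_gate()]; computed from the log's
#'   non-missing RT series when `NULL` (and left `NA` when the series is
#'   too short to gate).
#' @return An object of class `sit_post_error`: a list with `pes_ms`,
#'   `pcs_ms`, `pes_minus_pcs`, `robust_pes_ms`, `pea`, `pca`,
#'   `pes_detected_ms`, `pes_undetected_ms`, `pea_detected`,
#'   `pea_undetected`, `adf_p`, `method_used`, and the pair counts.
#' @export
post_error_measures <- function(log, gate = NULL) {
  .check_log(log)
  if (is.null(gate)) {
    rt <- log$rt_ms[!is.na(log$rt_ms)]
    gate <- if (length(rt) >= 30 && max(rt) > min(rt)) adf_gate(log$rt_ms) else NULL
  }
  pairs <- .post_pairs(log)
  if (is.null(pairs) || nrow(pairs$prev) == 0) {
    stop("Log has no eligible trial pairs.", call. = FALSE)
  }
  prev <- pairs$prev; post <- pairs$post
  ptype <- .prev_type(prev)
  rt_ok <- !post$is_timeout

  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  pes <- mean_or_na(post$rt_ms[ptype == "error" & rt_ok])
  pcs <- mean_or_na(post$rt_ms[ptype == "correct" & rt_ok])
  post_ok <- !post$is_timeout & post$is_correct   # timeouts count as not correct
  pea <- mean_or_na(post_ok[ptype == "error"])
  pca <- mean_or_na(post_ok[ptype == "correct"])

  det_prev <- .detected(prev$rating)
  pes_det <- mean_or_na(post$rt_ms[ptype == "error" & rt_ok & det_prev])
  pes_undet <- mean_or_na(post$rt_ms[ptype == "error" & rt_ok &
                                       .undetected(prev$rating)])
  pea_det <- mean_or_na(post_ok[ptype == "error" & det_prev])
  pea_undet <- mean_or_na(post_ok[ptype == "error" & .undetected(prev$rating)])

  # Matched pre/post difference over error episodes with valid flanks.
  ord <- order(log$global_trial_index)
  slog <- log[ord, ]
  n <- nrow(slog)
  rob <- NA_real_
  if (n >= 3) {
    mid <- 2:(n - 1)
    is_err <- !slog$is_timeout & !slog$is_correct
    elig <- is_err[mid] &
      slog$block_index[mid - 1] == slog$block_index[mid] &
      slog$block_index[mid + 1] == slog$block_index[mid] &
      slog$global_trial_index[mid] - slog$global_trial_index[mid - 1] == 1 &
      slog$global_trial_index[mid + 1] - slog$global_trial_index[mid] == 1 &
      !slog$is_timeout[mid - 1] & !slog$is_timeout[mid + 1]
    if (any(elig)) {
      rob <- mean(slog$rt_ms[mid + 1][elig] - slog$rt_ms[mid - 1][elig])
    }
  }

  structure(list(
    pes_ms = pes, pcs_ms = pcs, pes_minus_pcs = pes - pcs,
    robust_pes_ms = rob,
    pea = pea, pca = pca,
    pes_detected_ms = pes_det, pes_undetected_ms = pes_undet,
    pea_detected = pea_det, pea_undetected = pea_undet,
    n_post_error = sum(ptype == "error" & rt_ok),
    n_post_correct = sum(ptype == "correct" & rt_ok),
    adf_p = if (is.null(gate)) NA_real_ else gate$p_value,
    method_used = if (is.null(gate)) NA_character_ else gate$method_used
  ), class = "sit_post_error")
}

#' @export
print.sit_post_error <- function(x, ...) {
  cat(sprintf("<sit_post_error> PES %.1f ms, PCS %.1f ms (diff %.1f; %s), PEA %.3f, PCA %.3f\n",
              x$pes_ms, x$pcs_ms, x$pes_minus_pcs,
              x$method_used %||% "ungated", x$pea, x$pca))
  invisible(x)
}

#' Post-timeout speeding
#'
#' Mean RT of (non-timeout) trials directly following a timeout minus the
#' mean RT of trials following a correct response, under the same pair
#' eligibility rules as [post_error_measures()]. Negative differences mean
#' responses speed up after timeouts.
#'
#' @param log A trial-log tibble.
#' @return A list with `post_timeout_rt_ms`, `post_correct_rt_ms`,
#'   `difference_ms` and the pair counts; values are `NA` when no eligible
#'   pairs exist.
#' @export
post_timeout_speeding <- function(log) {
  .check_log(log)
  pairs <- .post_pairs(log)
  if (is.null(pairs)) {
    return(list(post_timeout_rt_ms = NA_real_, post_correct_rt_ms = NA_real_,
                difference_ms = NA_real_, n_post_timeout = 0L, n_post_correct = 0L))
  }
  ptype <- .prev_type(pairs$prev)
  rt_ok <- !pairs$post$is_timeout
  pt <- pairs$post$rt_ms[ptype == "timeout" & rt_ok]
  pc <- pairs$post$rt_ms[ptype == "correct" & rt_ok]
  list(
    post_timeout_rt_ms = if (length(pt)) mean(pt) else NA_real_,
    post_correct_rt_ms = if (length(pc)) mean(pc) else NA_real_,
    difference_ms = if (length(pt) && length(pc)) mean(pt) - mean(pc) else NA_real_,
    n_post_timeout = length(pt), n_post_correct = length(pc)
  )
}

#' Classify rule-1 error sources
#'
#' A rule-1 error is a rule-2 misapplication when the chosen target is the
#' trial's lure (the unique target fully absent from the stimulus) --
#' i.e. the participant applied rule 2 although rule 1 was required. All
#' other rule-1 errors form the complement class. Requires the extended log
#' schema with per-trial `lure_target`.
#'
#' @param log A trial-log tibble with a non-missing `lure_target` column.
#' @return A list with `trials` (rule-1 errors with a `class` column),
#'   `summary` (per-class n, share among rule-1 errors, detection rate),
#'   and `misapplication_share`.
#' @export
classify_error_sources <- function(log) {
  .check_log(log)
  if (!"lure_target" %in% names(log) || all(is.na(log$lure_target))) {
    stop("Log lacks the `lure_target` column needed for error-source ",
         "classification (extended schema).", call. = FALSE)
  }
  r1e <- log[log$required_rule == 1 & !log$is_timeout & !log$is_correct, ]
  r1e$class <- ifelse(r1e$chosen_target == r1e$lure_target,
                      "rule2_misapplication", "other")
  summary <- dplyr::bind_rows(lapply(c("rule2_misapplication", "other"), function(cl) {
    sub <- r1e[r1e$class == cl, ]
    rated <- .rated(sub$rating)
    tibble::tibble(
      class = cl, n = nrow(sub),
      share = if (nrow(r1e)) nrow(sub) / nrow(r1e) else NA_real_,
      detection_rate = if (any(rated)) sum(.detected(sub$rating)) / sum(rated)
                       else NA_real_
    )
  }))
  list(trials = r1e, summary = summary,
       misapplication_share = summary$share[summary$class == "rule2_misapplication"])
}

#' Participant inclusion criterion
#'
#' Error-awareness analyses require enough trials of both error types:
#' a participant is eligible when at least `min_per_type` detected *and*
#' `min_per_type` undetected errors are available (missing ratings do not
#' count towards either type).
#'
#' @param log A trial-log tibble.
#' @param min_per_type Minimum per error type (default 6; the bound is
#'   inclusive).
#' @return A list with `eligible`, `n_detected`, `n_undetected`.
#' @export
inclusion_check <- function(log, min_per_type = 6) {
  .check_log(log)
  err <- !log$is_timeout & !log$is_correct
  n_det <- sum(err & .detected(log$rating))
  n_undet <- sum(err & .undetected(log$rating))
  list(eligible = n_det >= min_per_type && n_undet >= min_per_type,
       n_detected = n_det, n_undetected = n_undet)
}

#' Parse a part specification
#'
#' @param parts A list of block-index vectors or a string like
#'   `"1-5,6-10,11-15"`.
#' @param n_blocks Number of blocks the specification must not exceed.
#' @return A named list of integer block vectors.
#' @export
parse_parts <- function(parts, n_blocks = NULL) {
  if (is.character(parts) && length(parts) == 1) {
    parts <- lapply(strsplit(parts, ",")[[1]], function(tok) {
      rng <- as.integer(strsplit(trimws(tok), "-")[[1]])
      if (anyNA(rng) || length(rng) > 2) {
        stop("Cannot parse part token '", tok, "'.", call. = FALSE)
      }
      if (length(rng) == 1) rng else rng[1]:rng[2]
    })
  }
  stopifnot(is.list(parts), length(parts) >= 1)
  parts <- lapply(parts, as.integer)
  all_blocks <- unlist(parts)
  if (anyDuplicated(all_blocks)) {
    stop("Parts overlap: block(s) ",
         paste(unique(all_blocks[duplicated(all_blocks)]), collapse = ", "),
         " appear in more than one part.", call. = FALSE)
  }
  if (!is.null(n_blocks) && any(all_blocks > n_blocks)) {
    stop("Part specification references blocks beyond ", n_blocks, ".",
         call. = FALSE)
  }
  stats::setNames(parts, paste0("part", seq_along(parts)))
}

#' Part-wise aggregates and paired contrasts
#'
#' Averages the response and detection rates within each part (a set of
#' blocks) for every participant and, given a cohort of logs, contrasts
#' each part against the baseline part with paired t-tests (mean
#' difference, t, df, p, Cohen's d). With a single log the per-part
#' aggregates are returned and the test statistics are `NA`.
#'
#' @param logs A trial-log tibble or a list of them (one per participant).
#' @param parts Part specification, see [parse_parts()].
#' @param baseline Index of the baseline part (default 1).
#' @return A list with `per_part` (participant x part x measure tibble),
#'   `cohort_means`, and `contrasts`.
#' @export
part_contrasts <- function(logs, parts, baseline = 1) {
  if (inherits(logs, "data.frame")) logs <- list(logs)
  n_blocks <- max(vapply(logs, function(l) max(l$block_index), numeric(1)))
  parts <- parse_parts(parts, n_blocks)
  stopifnot(baseline >= 1, baseline <= length(parts))

  per_part <- dplyr::bind_rows(lapply(seq_along(logs), function(j) {
    rr <- response_rates(logs[[j]], parts = parts)
    dplyr::bind_cols(
      tibble::tibble(participant = logs[[j]]$participant_id[1] %||% as.character(j)),
      rr$by_part
    )
  }))

  measures <- c("correct_rate", "error_rate", "timeout_rate",
                "error_detection_rate", "correct_detection_rate")
  cohort_means <- dplyr::summarise(
    dplyr::group_by(per_part, .data$part),
    dplyr::across(dplyr::all_of(measures), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )

  contrasts <- dplyr::bind_rows(lapply(
    setdiff(seq_along(parts), baseline), function(p) {
    dplyr::bind_rows(lapply(measures, function(m) {
      a <- per_part[[m]][per_part$part == p]
      b <- per_part[[m]][per_part$part == baseline]
      keep <- !is.na(a) & !is.na(b)
      a <- a[keep]; b <- b[keep]
      d <- a - b
      if (length(d) >= 2 && sd(d) > 0) {
        tt <- t.test(a, b, paired = TRUE)
        tibble::tibble(part = p, baseline = baseline, measure = m,
                       n = length(d), mean_diff = mean(d),
                       t = unname(tt$statistic), df = unname(tt$parameter),
                       p_value = tt$p.value, cohen_d = mean(d) / sd(d))
      } else {
        tibble::tibble(part = p, baseline = baseline, measure = m,
                       n = length(d),
                       mean_diff = if (length(d)) mean(d) else NA_real_,
                       t = NA_real_, df = NA_real_, p_value = NA_real_,
                       cohen_d = NA_real_)
      }
    }))
  }))
  list(per_part = per_part, cohort_means = cohort_means, contrasts = contrasts)
}
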