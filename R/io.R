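# Trial-log file format: UTF-8 CSV with a comment header carrying the
# schema version and seed provenance, e.g.
#   # sit-trial-log v1
#   # seed: 7
# Flags are written as 0/1, milliseconds as reals, missing values empty.

.log_version <- "sit-trial-log v1"

#' Columns of the trial-log schema
#'
#' @return Character vector of the versioned column list, in order.
#' @export
trial_log_columns <- function() {
  c("participant_id", "session_id",
    "block_index", "trial_index_in_block", "global_trial_index",
    "required_rule", "correct_target", "lure_target",
    "item1_category", "item1_colour", "item1_exemplar", "item1_scale", "item1_tilt",
    "item2_category", "item2_colour", "item2_exemplar", "item2_scale", "item2_tilt",
    "chosen_target", "rt_ms", "is_timeout", "is_correct",
    "rating", "eval_correct", "threshold_at_trial_ms", "points_earned",
    "iti_ms", "clock_onset_ms")
}

# Validates a trial-log tibble; stops with the offending column/row.
.check_log <- function(log) {
  if (!inherits(log, "data.frame") || nrow(log) == 0) {
    stop("Trial log must be a non-empty data frame.", call. = FALSE)
  }
  missing_cols <- setdiff(trial_log_columns(), names(log))
  if (length(missing_cols)) {
    stop("Trial log is missing column(s): ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  bad_rating <- which(!log$rating %in% .sit_ratings)
  if (length(bad_rating)) {
    stop("Invalid `rating` value in row(s) ",
         paste(head(bad_rating, 5), collapse = ", "), ".", call. = FALSE)
  }
  bad_rt <- which(is.na(log$rt_ms) != log$is_timeout)
  if (length(bad_rt)) {
    stop("`rt_ms` must be missing exactly on timeout trials; violated in ",
         "row(s) ", paste(head(bad_rt, 5), collapse = ", "), ".", call. = FALSE)
  }
  bad_miss <- which(log$rating == "missing" & !is.na(log$eval_correct))
  if (length(bad_miss)) {
    stop("`eval_correct` must be missing when the rating is missing; ",
         "violated in row(s) ", paste(head(bad_miss, 5), collapse = ", "), ".",
         call. = FALSE)
  }
  invisible(log)
}

#' Write / read a trial log
#'
#' Lossless CSV round trip of a trial log with a schema-version comment
#' line and optional seed provenance in the header. Readers reject unknown
#' schema versions and validate the column set, the rating levels and the
#' rt/timeout invariant, naming the offending column or rows.
#'
#' @param log A trial-log tibble (e.g. from [run_session()]).
#' @param path File path.
#' @param seed Optional integer recorded as provenance in the header.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns the trial-log tibble.
#' @export
write_trial_log <- function(log, path, seed = NULL) {
  .check_log(log)
  log <- log[, trial_log_columns()]
  header <- paste0("# ", .log_version)
  if (!is.null(seed)) header <- c(header, paste0("# seed: ", as.integer(seed)))
  writeLines(header, path)
  out <- log
  out$is_timeout <- as.integer(out$is_timeout)
  out$is_correct <- as.integer(out$is_correct)
  out$eval_correct <- as.integer(out$eval_correct)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("# ", .log_version))) {
    stop("Unknown trial-log version line: '", first, "' (expected '# ",
         .log_version, "').", call. = FALSE)
  }
  log <- readr::read_csv(
    path, comment = "#", na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session_id = readr::col_character(),
      block_index = readr::col_integer(),
      trial_index_in_block = readr::col_integer(),
      global_trial_index = readr::col_integer(),
      required_rule = readr::col_integer(),
      correct_target = readr::col_character(),
      lure_target = readr::col_character(),
      item1_category = readr::col_character(),
      item1_colour = readr::col_character(),
      item1_exemplar = readr::col_integer(),
      item1_scale = readr::col_double(),
      item1_tilt = readr::col_double(),
      item2_category = readr::col_character(),
      item2_colour = readr::col_character(),
      item2_exemplar = readr::col_integer(),
      item2_scale = readr::col_double(),
      item2_tilt = readr::col_double(),
      chosen_target = readr::col_character(),
      rt_ms = readr::col_double(),
      is_timeout = readr::col_integer(),
      is_correct = readr::col_integer(),
      rating = readr::col_character(),
      eval_correct = readr::col_integer(),
      threshold_at_trial_ms = readr::col_double(),
      points_earned = readr::col_integer(),
      iti_ms = readr::col_double(),
      clock_onset_ms = readr::col_double()
    )
  )
  missing_cols <- setdiff(trial_log_columns(), names(log))
  if (length(missing_cols)) {
    stop("Trial-log file is missing column(s): ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  log$is_timeout <- log$is_timeout == 1L
  log$is_correct <- log$is_correct == 1L
  log$eval_correct <- ifelse(is.na(log$eval_correct), NA, log$eval_correct == 1L)
  .check_log(log)
  log
}

#' Write / read a session configuration as JSON
#'
#' @param config A `sit_config`.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `sit_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sit_config"))
  obj <- unclass(config)
  obj$engine <- unclass(obj$engine)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  eng <- do.call(engine_params, obj$engine[names(obj$engine) %in%
                                             names(formals(engine_params))])
  session_config(
    n_blocks = obj$n_blocks,
    trials_per_block = obj$trials_per_block,
    rule1_fraction = obj$rule1_fraction,
    counterbalance_id = obj$counterbalance_id,
    seed = obj$seed,
    engine = eng
  )
}

#' Cohort analysis report
#'
#' Runs the full analysis suite over a cohort of trial logs and returns a
#' tidy per-participant summary plus cohort-level aggregates; optionally
#' writes a CSV (per participant x measure) and a JSON report.
#'
#' @param logs A list of trial-log tibbles (or one tibble).
#' @param parts Optional part specification for [part_contrasts()].
#' @param baseline Baseline part index.
#' @param out_dir Optional directory to write `participants.csv` and
#'   `report.json` into.
#' @return A list with `participants` (tibble), `cohort` (named list of
#'   cohort means) and `part_contrasts` (or `NULL`).
#' @export
analyze_cohort <- function(logs, parts = NULL, baseline = 1, out_dir = NULL) {
  if (inherits(logs, "data.frame")) logs <- list(logs)
  participants <- dplyr::bind_rows(lapply(logs, function(log) {
    rr <- response_rates(log)$overall
    pe <- post_error_measures(log)
    rules <- split_by_rule(log)
    inc <- inclusion_check(log)
    es <- tryCatch(classify_error_sources(log)$misapplication_share,
                   error = function(e) NA_real_)
    pts <- post_timeout_speeding(log)
    tibble::tibble(
      participant_id = log$participant_id[1],
      n_trials = rr$n_trials,
      correct_rate = rr$correct_rate, error_rate = rr$error_rate,
      timeout_rate = rr$timeout_rate,
      error_detection_rate = rr$error_detection_rate,
      correct_detection_rate = rr$correct_detection_rate,
      detection_rule1 = rules$detection_rate[rules$rule == 1],
      detection_rule2 = rules$detection_rate[rules$rule == 2],
      misapplication_share = es,
      pes_ms = pe$pes_ms, pcs_ms = pe$pcs_ms,
      pes_minus_pcs = pe$pes_minus_pcs, robust_pes_ms = pe$robust_pes_ms,
      pea = pe$pea, pca = pe$pca,
      adf_p = pe$adf_p, pes_method = pe$method_used,
      post_timeout_speeding_ms = pts$difference_ms,
      eligible = inc$eligible,
      n_detected = inc$n_detected, n_undetected = inc$n_undetected,
      score = attr(log, "score") %||% sum(log$points_earned)
    )
  }))
  num <- vapply(participants, is.numeric, logical(1))
  cohort <- as.list(colMeans(participants[, num], na.rm = TRUE))
  pc <- if (!is.null(parts)) part_contrasts(logs, parts, baseline) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(participants, file.path(out_dir, "participants.csv"), na = "")
    report <- list(cohort = cohort,
                   part_contrasts = if (!is.null(pc)) pc$contrasts else NULL)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(participants = participants, cohort = cohort, part_contrasts = pc)
}
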