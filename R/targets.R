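#' Build a counterbalanced target set
#'
#' The task uses four constant targets, each a category--colour pairing
#' (e.g. a blue ball). Categories always occupy the same spatial positions
#' (left to right) and map position-wise onto the four response fingers;
#' only the colour--category assignment rotates across participants so that
#' every colour can end up on every finger.
#'
#' The 24 possible colour assignments are indexed by `counterbalance_id`
#' (0 to 23) in lexicographic order of the colour sequence over the fixed
#' category order `ball, ice_cream, chair, bird` with colours sorted
#' alphabetically (`blue < green < red < yellow`). Id 0 therefore yields the
#' assignment blue ball, green ice cream, red chair, yellow bird.
#'
#' @param counterbalance_id Integer in 0..23 selecting a colour permutation.
#' @return An object of class `sit_target_set`: a list with `categories`
#'   (spatial order), `colour_of` (named character, category -> colour),
#'   `button_of` (named character, category -> finger label) and
#'   `counterbalance_id`.
#' @examples
#' ts <- build_target_set(0)
#' ts$colour_of[["ball"]]
#' @export
build_target_set <- function(counterbalance_id = 0) {
  if (!is.numeric(counterbalance_id) || length(counterbalance_id) != 1 ||
      is.na(counterbalance_id) || counterbalance_id != round(counterbalance_id) ||
      counterbalance_id < 0 || counterbalance_id > 23) {
    stop("`counterbalance_id` must be a single integer in 0..23.", call. = FALSE)
  }
  colours <- .permutation_unrank(.sit_colours, as.integer(counterbalance_id))
  structure(
    list(
      categories = .sit_categories,
      colour_of = stats::setNames(colours, .sit_categories),
      button_of = stats::setNames(.sit_buttons, .sit_categories),
      counterbalance_id = as.integer(counterbalance_id)
    ),
    class = "sit_target_set"
  )
}

# Lexicographic unranking (factorial number system) of a permutation of
# `items`; rank 0 is the identity over the sorted items.
.permutation_unrank <- function(items, rank) {
  n <- length(items)
  pool <- sort(items)
  out <- character(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    idx <- rank %/% f
    rank <- rank %% f
    out[i] <- pool[idx + 1]
    pool <- pool[-(idx + 1)]
  }
  out
}

#' @export
print.sit_target_set <- function(x, ...) {
  cat("<sit_target_set> counterbalance_id =", x$counterbalance_id, "\n")
  for (cat_i in x$categories) {
    cat(sprintf("  %-9s %-7s [%s]\n", cat_i, x$colour_of[[cat_i]], x$button_of[[cat_i]]))
  }
  invisible(x)
}

#' Session configuration
#'
#' Describes one session of the task: how many blocks, how many trials per
#' block, the planned fraction of rule-1 trials in each block, which
#' colour counterbalancing to use, the master seed, and the engine (timing,
#' adaptive-deadline and scoring) parameters.
#'
#' Exact balancing is required: `rule1_fraction * trials_per_block` must be
#' an integer for every block, and `trials_per_block` must be divisible by 4
#' so each target can be the correct response equally often.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block (default 32).
#' @param rule1_fraction Fraction of trials per block that require rule 1;
#'   scalar (recycled) or one value per block.
#' @param counterbalance_id Colour assignment index, see [build_target_set()].
#' @param seed Master seed for plan generation and simulation.
#' @param engine Engine parameters, see [engine_params()].
#' @return An object of class `sit_config`.
#' @seealso [study1_config()], [study2_config()], [build_session()]
#' @export
session_config <- function(n_blocks,
                           trials_per_block = 32,
                           rule1_fraction = 0.5,
                           counterbalance_id = 0,
                           seed = 1,
                           engine = engine_params()) {
  stopifnot(is.numeric(n_blocks), length(n_blocks) == 1, n_blocks >= 1,
            is.numeric(trials_per_block), trials_per_block >= 4)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (trials_per_block %% 4 != 0) {
    stop("`trials_per_block` must be divisible by 4 (equal correct-target counts).",
         call. = FALSE)
  }
  if (length(rule1_fraction) == 1) rule1_fraction <- rep(rule1_fraction, n_blocks)
  if (length(rule1_fraction) != n_blocks) {
    stop("`rule1_fraction` must have length 1 or `n_blocks`.", call. = FALSE)
  }
  if (any(rule1_fraction < 0 | rule1_fraction > 1)) {
    stop("`rule1_fraction` values must lie in [0, 1].", call. = FALSE)
  }
  k <- rule1_fraction * trials_per_block
  bad <- which(abs(k - round(k)) > 1e-9)
  if (length(bad)) {
    stop("rule1_fraction x trials_per_block is not an integer in block(s) ",
         paste(bad, collapse = ", "), ".", call. = FALSE)
  }
  cfg <- structure(
    list(
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      rule1_fraction = as.numeric(rule1_fraction),
      counterbalance_id = as.integer(counterbalance_id),
      seed = as.integer(seed),
      engine = engine
    ),
    class = "sit_config"
  )
  cfg
}

#' Canned study configurations
#'
#' `study1_config()` reproduces the first study's design: 14 blocks of 32
#' trials (448 in total) with both rules required equally often in every
#' block. `study2_config()` reproduces the second study's design: 15 blocks
#' of 32 trials (480 in total) in three fixed parts of five blocks each with
#' rule-1 fractions 50%, 25% and 75%.
#'
#' @param seed Master seed.
#' @param counterbalance_id Colour assignment index.
#' @param engine Engine parameters.
#' @return A `sit_config`.
#' @export
study1_config <- function(seed = 1, counterbalance_id = 0, engine = engine_params()) {
  session_config(n_blocks = 14, trials_per_block = 32, rule1_fraction = 0.5,
                 counterbalance_id = counterbalance_id, seed = seed, engine = engine)
}

#' @rdname study1_config
#' @export
study2_config <- function(seed = 1, counterbalance_id = 0, engine = engine_params()) {
  session_config(n_blocks = 15, trials_per_block = 32,
                 rule1_fraction = rep(c(0.5, 0.25, 0.75), each = 5),
                 counterbalance_id = counterbalance_id, seed = seed, engine = engine)
}

#' Block-to-part assignment of a study-2 style session
#'
#' @param config A `sit_config` or a number of blocks.
#' @param part_size Blocks per part (default 5).
#' @return Integer vector mapping block index to part number.
#' @export
part_of_block <- function(config, part_size = 5) {
  n <- if (inherits(config, "sit_config")) config$n_blocks else as.integer(config)
  ((seq_len(n) - 1) %/% part_size) + 1
}

#' Build a balanced session plan
#'
#' Generates the full, ordered trial schedule for a session. Within every
#' block each of the four targets is the correct response exactly
#' `trials_per_block / 4` times, and the number of rule-1 trials equals
#' `rule1_fraction * trials_per_block`. The joint rule-by-target cell counts
#' are additionally balanced as evenly as arithmetic allows (remainder cells
#' assigned at random). The per-block (rule, target) sequence is shuffled
#' with a seeded RNG and a stimulus satisfying the rule semantics is
#' composed for every trial.
#'
#' Each block uses the substream seed `config$seed + block_index`, so block
#' contents are stable if the plan is truncated or extended.
#'
#' @param config A `sit_config`.
#' @return An object of class `sit_plan`: list with `config`, `target_set`
#'   and `trials`, a tibble with one row per trial (block/trial indices,
#'   `required_rule`, `correct_target`, `lure_target` and the composed
#'   stimulus item columns `item1_*`, `item2_*`).
#' @examples
#' plan <- build_session(study1_config(seed = 7))
#' nrow(plan$trials)
#' @export
build_session <- function(config) {
  stopifnot(inherits(config, "sit_config"))
  target_set <- build_target_set(config$counterbalance_id)
  support <- stimulus_support(target_set)
  tpb <- config$trials_per_block
  per_target <- tpb %/% 4L

  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    withr::with_seed(config$seed + b, {
      k1 <- as.integer(round(config$rule1_fraction[b] * tpb))
      counts1 <- .allocate_evenly(k1, 4L)
      counts2 <- per_target - counts1
      if (any(counts2 < 0)) {
        # Can only occur for extreme fractions where even the most even
        # allocation overflows a target's quota.
        stop("Joint rule/target balance infeasible in block ", b, ".", call. = FALSE)
      }
      rule <- rep(c(1L, 2L), times = c(k1, tpb - k1))
      target <- c(rep(target_set$categories, times = counts1),
                  rep(target_set$categories, times = counts2))
      ord <- sample.int(tpb)
      rule <- rule[ord]
      target <- target[ord]
      stim <- lapply(seq_len(tpb), function(i) {
        compose_stimulus(rule[i], target[i], target_set, support = support)
      })
      tibble::tibble(
        block_index = b,
        trial_index_in_block = seq_len(tpb),
        required_rule = rule,
        correct_target = target,
        lure_target = vapply(stim, function(s) s$lure_target, character(1)),
        item1_category = vapply(stim, function(s) s$item1$category, character(1)),
        item1_colour = vapply(stim, function(s) s$item1$colour, character(1)),
        item1_exemplar = vapply(stim, function(s) s$item1$exemplar_id, integer(1)),
        item1_scale = vapply(stim, function(s) s$item1$scale, numeric(1)),
        item1_tilt = vapply(stim, function(s) s$item1$tilt_deg, numeric(1)),
        item2_category = vapply(stim, function(s) s$item2$category, character(1)),
        item2_colour = vapply(stim, function(s) s$item2$colour, character(1)),
        item2_exemplar = vapply(stim, function(s) s$item2$exemplar_id, integer(1)),
        item2_scale = vapply(stim, function(s) s$item2$scale, numeric(1)),
        item2_tilt = vapply(stim, function(s) s$item2$tilt_deg, numeric(1))
      )
    })
  })
  trials <- dplyr::bind_rows(blocks)
  trials$global_trial_index <- seq_len(nrow(trials))
  trials <- dplyr::relocate(trials, "global_trial_index", .after = "trial_index_in_block")
  structure(list(config = config, target_set = target_set, trials = trials),
            class = "sit_plan")
}

# Split `total` into `cells` non-negative integers that are as equal as
# possible; the remainder is assigned to randomly chosen cells.
.allocate_evenly <- function(total, cells) {
  base <- total %/% cells
  counts <- rep(base, cells)
  r <- total - base * cells
  if (r > 0) {
    extra <- sample.int(cells, r)
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

#' @export
print.sit_plan <- function(x, ...) {
  cat(sprintf("<sit_plan> %d blocks x %d trials = %d trials (seed %d, counterbalance %d)\n",
              x$config$n_blocks, x$config$trials_per_block, nrow(x$trials),
              x$config$seed, x$config$counterbalance_id))
  invisible(x)
}
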