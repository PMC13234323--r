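#' Normative rule semantics of a two-item stimulus
#'
#' Each trial shows two items, each a (category, colour) mixture of the
#' target features. Two rules apply in a hierarchical order:
#'
#' * Rule 1: if an item matches a target in both category *and* colour, that
#'   target is correct. Rule 1 always takes precedence.
#' * Rule 2: only if no item fully matches a target, the correct target is
#'   the one whose category and colour are both absent from the two items.
#'
#' `classify_stimulus()` inverts this composition for arbitrary item pairs.
#' It never throws for strange inputs: pairs with zero or multiple full
#' matches, or without a unique fully-absent target, are reported as
#' ill-formed with a reason code.
#'
#' @param items A list of two items, each a list (or named character vector)
#'   with `category` and `colour`.
#' @param target_set A `sit_target_set`.
#' @return A list with `well_formed` (logical); when well-formed also
#'   `rule` (1 or 2), `correct_target` and `lure_target`; otherwise a
#'   `reason` code (`"multiple_matches"`, `"no_unique_lure"`).
#' @examples
#' ts <- build_target_set(0)
#' classify_stimulus(list(list(category = "ice_cream", colour = "green"),
#'                        list(category = "chair", colour = "yellow")), ts)
#' @export
classify_stimulus <- function(items, target_set) {
  stopifnot(inherits(target_set, "sit_target_set"), length(items) == 2)
  cats <- vapply(items, function(i) as.character(i[["category"]]), character(1))
  cols <- vapply(items, function(i) as.character(i[["colour"]]), character(1))
  matches <- target_set$categories[
    vapply(target_set$categories, function(tc) {
      any(cats == tc & cols == target_set$colour_of[[tc]])
    }, logical(1))
  ]
  absent <- target_set$categories[
    vapply(target_set$categories, function(tc) {
      !(tc %in% cats) && !(target_set$colour_of[[tc]] %in% cols)
    }, logical(1))
  ]
  if (length(absent) != 1) {
    return(list(well_formed = FALSE, reason = "no_unique_lure"))
  }
  if (length(matches) > 1) {
    return(list(well_formed = FALSE, reason = "multiple_matches"))
  }
  if (length(matches) == 1) {
    list(well_formed = TRUE, rule = 1L, correct_target = matches, lure_target = absent)
  } else {
    list(well_formed = TRUE, rule = 2L, correct_target = absent, lure_target = absent)
  }
}

#' The unique fully-absent (lure) target of an item pair
#'
#' For every well-formed stimulus there is exactly one target whose category
#' and colour are both absent from the two items. On rule-2 trials this is
#' the correct target; on rule-1 trials it is the lure whose choice
#' constitutes a rule-2 misapplication.
#'
#' @inheritParams classify_stimulus
#' @return The lure category, or `NA_character_` if zero or several targets
#'   are fully absent.
#' @export
lure_of <- function(items, target_set) {
  stopifnot(inherits(target_set, "sit_target_set"), length(items) == 2)
  cats <- vapply(items, function(i) as.character(i[["category"]]), character(1))
  cols <- vapply(items, function(i) as.character(i[["colour"]]), character(1))
  absent <- target_set$categories[
    vapply(target_set$categories, function(tc) {
      !(tc %in% cats) && !(target_set$colour_of[[tc]] %in% cols)
    }, logical(1))
  ]
  if (length(absent) == 1) absent else NA_character_
}

#' Enumerate all feasible stimulus feature assignments
#'
#' Brute-forces the 256 ordered pairs of (category, colour) items and keeps
#' those that satisfy the stimulus invariants: the two items have distinct
#' categories, exactly one target is fully absent, and the classifier
#' returns a well-formed (rule, correct target) pair. The result is the
#' exact support from which [compose_stimulus()] draws uniformly.
#'
#' @param target_set A `sit_target_set`.
#' @return A tibble with columns `item1_category`, `item1_colour`,
#'   `item2_category`, `item2_colour`, `rule`, `correct_target`,
#'   `lure_target`.
#' @export
stimulus_support <- function(target_set) {
  stopifnot(inherits(target_set, "sit_target_set"))
  grid <- expand.grid(
    item1_category = .sit_categories, item1_colour = .sit_colours,
    item2_category = .sit_categories, item2_colour = .sit_colours,
    stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    if (g$item1_category == g$item2_category) return(NULL)
    cls <- classify_stimulus(
      list(list(category = g$item1_category, colour = g$item1_colour),
           list(category = g$item2_category, colour = g$item2_colour)),
      target_set
    )
    if (!cls$well_formed) return(NULL)
    cbind(g, rule = cls$rule, correct_target = cls$correct_target,
          lure_target = cls$lure_target)
  })
  tibble::as_tibble(do.call(rbind, res))
}

#' Compose a stimulus for a requested rule and correct target
#'
#' Draws uniformly from the set of feature assignments that make exactly the
#' requested rule applicable with the requested correct target (see
#' [stimulus_support()]); the item order within the pair is part of the
#' enumerated support, so left/right placement is random. Visual metadata
#' (exemplar 1..7, scale 0.4..1, tilt -40..40 degrees) is sampled
#' independently; it is logged but has no computational effect.
#'
#' Draws use the current RNG state; seed via `set.seed()` or
#' [withr::with_seed()] for reproducibility.
#'
#' @param rule 1 or 2.
#' @param correct_target A category in the target set.
#' @param target_set A `sit_target_set`.
#' @param support Optional precomputed [stimulus_support()] table (an
#'   optimisation for bulk composition).
#' @return A list of class `sit_stimulus` with `item1`, `item2` (each with
#'   `category`, `colour`, `exemplar_id`, `scale`, `tilt_deg`), `rule`,
#'   `correct_target` and `lure_target`.
#' @export
compose_stimulus <- function(rule, correct_target, target_set, support = NULL) {
  stopifnot(rule %in% c(1, 2))
  if (!correct_target %in% target_set$categories) {
    stop("`correct_target` must be one of: ",
         paste(target_set$categories, collapse = ", "), call. = FALSE)
  }
  if (is.null(support)) support <- stimulus_support(target_set)
  sub <- support[support$rule == rule & support$correct_target == correct_target, ]
  if (nrow(sub) == 0) {
    stop("Empty composition support for rule ", rule, " / ", correct_target,
         " - invalid target set?", call. = FALSE)
  }
  row <- sub[sample.int(nrow(sub), 1), ]
  mk_item <- function(category, colour) {
    list(category = category, colour = colour,
         exemplar_id = sample.int(7L, 1),
         scale = runif(1, 0.4, 1.0),
         tilt_deg = runif(1, -40, 40))
  }
  structure(
    list(
      item1 = mk_item(row$item1_category, row$item1_colour),
      item2 = mk_item(row$item2_category, row$item2_colour),
      rule = as.integer(rule),
      correct_target = row$correct_target,
      lure_target = row$lure_target
    ),
    class = "sit_stimulus"
  )
}

#' @export
print.sit_stimulus <- function(x, ...) {
  cat(sprintf("<sit_stimulus> rule %d, correct = %s, lure = %s\n",
              x$rule, x$correct_target, x$lure_target))
  cat(sprintf("  item1: %s %s  item2: %s %s\n",
              x$item1$colour, x$item1$category, x$item2$colour, x$item2$category))
  invisible(x)
}
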