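# Extreme-groups selection with boundary-tie expansion.

#' Select extreme groups on a score
#'
#' Implements the extreme-groups protocol: the `k` lowest and `k` highest
#' scorers form the low and high groups. With `tie_policy = "expand"` every
#' subject tied at a boundary value is included, so a group may exceed `k`
#' (e.g. three subjects tied at the older age boundary make an 11-member
#' group for k = 10). With `"strict"` group sizes are exactly `k` and the
#' choice among boundary ties is made by a seeded draw and reported.
#'
#' @param subjects Subject table with a `subject_id` column and the score
#'   column.
#' @param k Nominal group size.
#' @param score_field Column to rank on, e.g. `"vviq_total"` or
#'   `"age_years"`.
#' @param tie_policy `"expand"` (default) or `"strict"`.
#' @param labels Length-2 character, labels for the low and high groups
#'   (default `c("low", "high")`; use e.g. `c("younger", "older")` for age).
#' @param seed Seed for the tie draw in strict mode.
#' @return Object of class `group_assignment`: `assignment` (data frame
#'   `subject_id`, `score`, `label`), `gap` (min high score minus max low
#'   score), `n_low`, `n_high`, `tie_policy`, `tie_broken` (logical).
#' @details Assignment depends only on score values, never on input order,
#'   so it is permutation-invariant (in strict mode, up to the seeded draw,
#'   which ranks tied subjects by `subject_id` before drawing).
#' @export
select_extreme_groups <- function(subjects, k = 10,
                                  score_field = "vviq_total",
                                  tie_policy = c("expand", "strict"),
                                  labels = c("low", "high"), seed = 1) {
  tie_policy <- match.arg(tie_policy)
  if (!score_field %in% names(subjects))
    stop("score_field '", score_field, "' not found", call. = FALSE)
  score <- subjects[[score_field]]
  if (anyNA(score)) stop("scores must be present for all subjects",
                         call. = FALSE)
  n <- nrow(subjects)
  if (2 * k > n)
    stop("2k = ", 2 * k, " exceeds the number of subjects (", n, ")",
         call. = FALSE)
  s_sorted <- sort(score)
  lo_bound <- s_sorted[k]          # low-group boundary value
  hi_bound <- s_sorted[n - k + 1]  # high-group boundary value
  tie_broken <- FALSE
  pick_boundary <- function(candidates, need) {
    # candidates: subject indices tied at the boundary; need: how many
    if (length(candidates) == need) return(candidates)
    tie_broken <<- TRUE
    ord <- candidates[order(subjects$subject_id[candidates])]
    set.seed(seed)
    sort(sample(ord, need))
  }
  if (tie_policy == "expand") {
    low_idx <- which(score <= lo_bound)
    high_idx <- which(score >= hi_bound)
  } else {
    low_sure <- which(score < lo_bound)
    low_idx <- c(low_sure, pick_boundary(which(score == lo_bound),
                                         k - length(low_sure)))
    high_sure <- which(score > hi_bound)
    high_idx <- c(high_sure, pick_boundary(which(score == hi_bound),
                                           k - length(high_sure)))
  }
  if (length(intersect(low_idx, high_idx)))
    stop("groups overlap after tie expansion (boundary values meet); ",
         "k = ", k, " is too large for this score distribution",
         call. = FALSE)
  gap <- min(score[high_idx]) - max(score[low_idx])
  if (gap < 0)
    stop("invalid assignment: high group minimum below low group maximum",
         call. = FALSE)
  label <- rep("none", n)
  label[low_idx] <- labels[1]
  label[high_idx] <- labels[2]
  structure(list(
    assignment = data.frame(subject_id = subjects$subject_id,
                            score = score, label = label,
                            stringsAsFactors = FALSE),
    gap = gap,
    n_low = length(low_idx), n_high = length(high_idx),
    tie_policy = tie_policy, tie_broken = tie_broken
  ), class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Extreme-group assignment (", x$tie_policy, " ties)\n", sep = "")
  cat("  low group n  =", x$n_low, "\n")
  cat("  high group n =", x$n_high, "\n")
  cat("  gap          =", x$gap, "\n")
  if (x$tie_broken) cat("  boundary ties resolved by seeded draw\n")
  invisible(x)
}

#' Attach extreme-group labels to a subject table
#'
#' Convenience wrapper: runs [select_extreme_groups()] and adds the label as
#' a new column (named `vviq_group` for the default score).
#'
#' @inheritParams select_extreme_groups
#' @param column Name of the new column.
#' @return `subjects` with the label column added.
#' @export
attach_group_labels <- function(subjects, k = 10,
                                score_field = "vviq_total",
                                tie_policy = "expand",
                                labels = c("low", "high"),
                                column = "vviq_group") {
  ga <- select_extreme_groups(subjects, k = k, score_field = score_field,
                              tie_policy = tie_policy, labels = labels)
  subjects[[column]] <- ga$assignment$label[match(subjects$subject_id,
                                                  ga$assignment$subject_id)]
  subjects
}
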