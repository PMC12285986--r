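# Composite statistics: Fisher's combined probability, the five-category
# ordering binomial, sign-consistency, 2x2 chi-squared, percent differences.

#' Fisher's method for combining p-values
#'
#' chi2 = -2 sum(log p) on 2k degrees of freedom.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return List with `chi2`, `df`, `p_combined`.
#' @export
fishers_method <- function(pvals) {
  if (!length(pvals) || any(pvals <= 0) || any(pvals > 1))
    stop("all p-values must lie in (0, 1]; p = 0 gives an infinite ",
         "statistic", call. = FALSE)
  chi2 <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(chi2 = chi2, df = df,
       p_combined = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Upper-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p). Computed through the distribution
#' function's log-space machinery, so tiny tails (far below 1e-40) do not
#' underflow when requested on the log scale.
#'
#' @param n Number of trials.
#' @param k Threshold count (0 <= k <= n).
#' @param p Per-trial success probability.
#' @param log10_p Return log10 of the tail probability instead.
#' @return Probability (or its log10).
#' @export
binomial_at_least <- function(n, k, p, log10_p = FALSE) {
  stopifnot(n >= 0, k >= 0, k <= n, p >= 0, p <= 1)
  if (k == 0) return(if (log10_p) 0 else 1)
  lp <- stats::pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  if (log10_p) lp / log(10) else exp(lp)
}

#' Sign-consistency test
#'
#' Upper-tail probability that at least `k_directional` of `n_regions`
#' independent comparisons fall in one direction under the
#' direction-symmetric null (p = 1/2); the sign-test tail.
#'
#' @param n_regions Number of comparisons.
#' @param k_directional Number that went in the predicted direction.
#' @param log10_p Return log10 of the probability.
#' @return Probability (or its log10).
#' @export
sign_consistency <- function(n_regions, k_directional, log10_p = FALSE) {
  binomial_at_least(n_regions, k_directional, 0.5, log10_p = log10_p)
}

#' Count regions matching a predicted ordering of five category means
#'
#' A region matches when its five values stand in the strict predicted
#' descending sequence: hyperphantasic individual largest, High-VVIQ group
#' mean second, whole-sample mean third, Low-VVIQ group mean fourth,
#' aphantasic individual smallest. Ties make a region a non-match (the
#' prediction is a strict order). Under independent random values a match is
#' a 1-in-5! = 1/120 event per region, and the tail probability of at least
#' `k` matches among `n` regions is binomial.
#'
#' @param category_values Data frame or matrix with one row per region and
#'   columns `hphant`, `high_group_mean`, `sample_mean`, `low_group_mean`,
#'   `aphant`. Row names (or a `region` column) identify regions.
#' @return List of class `ordering_test_result`: `n_regions`, `k_matches`,
#'   `per_trial_p` (1/120), `p_at_least_k`, `matched_regions`,
#'   `tied_regions`.
#' @export
ordering_match_count <- function(category_values) {
  cols <- c("hphant", "high_group_mean", "sample_mean", "low_group_mean",
            "aphant")
  x <- as.data.frame(category_values)
  if (!all(cols %in% names(x)))
    stop("category_values needs columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  region <- if ("region" %in% names(x)) as.character(x$region)
            else if (!is.null(rownames(x))) rownames(x)
            else as.character(seq_len(nrow(x)))
  v <- as.matrix(x[, cols])
  if (anyNA(v)) stop("all five category values must be present per region",
                     call. = FALSE)
  strict_desc <- v[, 1] > v[, 2] & v[, 2] > v[, 3] &
                 v[, 3] > v[, 4] & v[, 4] > v[, 5]
  has_tie <- apply(v, 1, function(r) anyDuplicated(r) > 0)
  n <- nrow(v)
  k <- sum(strict_desc)
  structure(list(
    n_regions = n, k_matches = k, per_trial_p = 1 / factorial(5),
    p_at_least_k = binomial_at_least(n, k, 1 / factorial(5)),
    matched_regions = region[strict_desc],
    tied_regions = region[has_tie]
  ), class = "ordering_test_result")
}

#' @export
print.ordering_test_result <- function(x, ...) {
  cat(sprintf("predicted ordering matched in %d of %d regions\n",
              x$k_matches, x$n_regions))
  cat(sprintf("per-region probability %.6f; P(at least %d) = %.4g\n",
              x$per_trial_p, x$k_matches, x$p_at_least_k))
  invisible(x)
}

#' 2x2 chi-squared test
#'
#' Pearson chi-squared on a 2x2 count table (df = 1), optionally with the
#' Yates continuity correction, which subtracts 0.5 from each
#' |observed - expected| before squaring (floored at 0).
#'
#' @param counts 2x2 matrix of nonnegative counts; all margins must be
#'   positive.
#' @param yates Apply the continuity correction.
#' @return List of class `chi2_result`: `chi2`, `df`, `p`,
#'   `yates_applied`, `expected`.
#' @export
chi2_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
    stop("counts must be a 2x2 nonnegative matrix", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin: expected cells undefined", call. = FALSE)
  expected <- outer(rs, cs) / n
  dev <- abs(counts - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 yates_applied = yates, expected = expected),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-squared(1) = %.4f, p = %.5g%s\n", x$chi2, x$p,
              if (x$yates_applied) " (Yates corrected)" else ""))
  invisible(x)
}

#' Signed percent difference under an explicit denominator convention
#'
#' 100 (other - reference) / denominator. The denominator convention is
#' mandatory because percent differences between two group means are
#' ambiguous without it; the convention used is returned alongside the
#' value.
#'
#' @param reference,other The two values being compared.
#' @param denominator `"reference"` (default), `"other"` or `"midpoint"`.
#' @return List with `percent` and `denominator`.
#' @export
percent_difference <- function(reference, other,
                               denominator = c("reference", "other",
                                               "midpoint")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator, reference = reference, other = other,
                midpoint = (reference + other) / 2)
  if (den == 0) stop("zero denominator", call. = FALSE)
  list(percent = 100 * (other - reference) / den, denominator = denominator)
}
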