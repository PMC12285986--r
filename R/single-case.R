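# Single case versus control sample: Bayesian effect-size inference with a
# closed-form frequentist oracle.

#' Bayesian single-case comparison against a control sample
#'
#' Compares one individual's score with a small control sample under the
#' standard noninformative-prior construction: per Monte-Carlo iteration the
#' control-population variance is drawn as
#' psi = (n - 1) s^2 / chi^2_(n-1), the mean as mu ~ N(x_bar, psi / n), and
#' the case is expressed as an effect size z = (x_case - mu) / sqrt(psi).
#' `p_below` estimates the proportion of the control population falling
#' below the case (mean of Phi(z) over iterations); the point effect size is
#' the median z and the 95% credible interval its 2.5/97.5 percentiles.
#'
#' @param x_case The case's score.
#' @param controls A [summary_stats()] object or a numeric vector of control
#'   scores (n >= 2, sd > 0).
#' @param n_iter Monte-Carlo iterations (>= 1e4).
#' @param seed Integer seed.
#' @return List of class `single_case_result`: `z_cc_point`, `z_cc_mean`,
#'   `z_cc_ci95`, `p_below`, `p_two_sided` (2 min(p_below, 1 - p_below)),
#'   `n_iter`, `seed`.
#' @seealso [crawford_howell_t()] for the closed-form frequentist
#'   counterpart, to which the two-sided Bayesian p converges.
#' @export
single_case_test <- function(x_case, controls, n_iter = 1e5, seed = 1) {
  if (is.numeric(controls)) controls <- as_summary_stats(controls)
  stopifnot(controls$n >= 2, n_iter >= 1e4)
  if (controls$sd == 0)
    stop("control sd is 0: posterior undefined", call. = FALSE)
  set.seed(seed)
  n <- controls$n
  psi <- (n - 1) * controls$sd^2 / stats::rchisq(n_iter, n - 1)
  mu <- stats::rnorm(n_iter, controls$mean, sqrt(psi / n))
  z <- (x_case - mu) / sqrt(psi)
  p_below <- mean(stats::pnorm(z))
  structure(list(
    z_cc_point = stats::median(z),
    z_cc_mean = mean(z),
    z_cc_ci95 = unname(stats::quantile(z, c(0.025, 0.975))),
    p_below = p_below,
    p_two_sided = 2 * min(p_below, 1 - p_below),
    n_iter = n_iter, seed = seed
  ), class = "single_case_result")
}

#' @export
print.single_case_result <- function(x, ...) {
  cat(sprintf("case-controls effect size %.4f [%.4f, %.4f]\n",
              x$z_cc_point, x$z_cc_ci95[1], x$z_cc_ci95[2]))
  cat(sprintf("estimated %% of controls below case: %.2f%%; ",
              100 * x$p_below))
  cat(sprintf("two-sided p = %.5g (%d iterations)\n",
              x$p_two_sided, x$n_iter))
  invisible(x)
}

#' Modified t-test for a single case versus controls
#'
#' Closed-form frequentist test treating the control sample as a sample, not
#' a population: t = (x_case - x_bar) / (s sqrt((n + 1) / n)) on n - 1
#' degrees of freedom. Serves as the analytic oracle for
#' [single_case_test()].
#'
#' @inheritParams single_case_test
#' @param tails 1 or 2.
#' @return List of class `t_test_result` with `t`, `df`, `p`, and the
#'   one-tailed lower-tail probability `p_below`.
#' @export
crawford_howell_t <- function(x_case, controls, tails = 2) {
  if (is.numeric(controls)) controls <- as_summary_stats(controls)
  stopifnot(controls$n >= 2, tails %in% c(1, 2))
  if (controls$sd == 0) stop("control sd is 0", call. = FALSE)
  n <- controls$n
  tstat <- (x_case - controls$mean) / (controls$sd * sqrt((n + 1) / n))
  df <- n - 1
  structure(list(t = tstat, df = df,
                 p = min(1, tails * stats::pt(-abs(tstat), df)),
                 p_below = stats::pt(tstat, df),
                 ci95 = c(NA_real_, NA_real_),
                 d = (x_case - controls$mean) / controls$sd,
                 tails = tails, variance = "case-controls"),
            class = "t_test_result")
}
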