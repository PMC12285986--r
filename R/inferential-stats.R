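# Summary-statistic t-tests, Pearson correlation, and split-plot mixed
# ANOVA with Type III sums of squares and partial eta squared.

#' Summary statistics of one sample
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Sample size (>= 2).
#' @return Object of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

#' Summary statistics from raw data
#' @param x Numeric vector, length >= 2.
#' @return Object of class `summary_stats`.
#' @export
as_summary_stats <- function(x) {
  x <- x[!is.na(x)]
  summary_stats(mean(x), stats::sd(x), length(x))
}

#' Two-sample t-test from summary statistics
#'
#' Independent-samples t-test computed from means, standard deviations and
#' sample sizes, so that printed group summaries can be tested directly.
#' The sign of `t` follows `a$mean - b$mean`.
#'
#' @param a,b [summary_stats()] objects (or lists with `mean`, `sd`, `n`).
#' @param variance `"pooled"` (df = n1 + n2 - 2, variances weighted by
#'   n - 1) or `"welch"` (Satterthwaite df).
#' @param tails 1 or 2.
#' @return List of class `t_test_result`: `t`, `df`, `p`, `ci95` (95%
#'   two-sided CI on the mean difference), `d` (Cohen's d with pooled sd),
#'   `tails`, `variance`.
#' @export
t_from_summary <- function(a, b, variance = c("pooled", "welch"), tails = 2) {
  variance <- match.arg(variance)
  stopifnot(tails %in% c(1, 2))
  m1 <- a$mean; s1 <- a$sd; n1 <- a$n
  m2 <- b$mean; s2 <- b$sd; n2 <- b$n
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (s1 == 0 && s2 == 0) {
    if (m1 != m2)
      stop("both groups have zero sd with unequal means: ",
           "t statistic infinite", call. = FALSE)
    return(structure(list(t = 0, df = n1 + n2 - 2, p = 1, ci95 = c(0, 0),
                          d = 0, tails = tails, variance = variance),
                     class = "t_test_result"))
  }
  if (variance == "pooled") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- tails * stats::pt(-abs(tstat), df)
  ci <- (m1 - m2) + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(t = tstat, df = df, p = min(p, 1), ci95 = ci,
                 d = (m1 - m2) / sqrt(sp2), tails = tails,
                 variance = variance),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.4f, p = %.5g (%d-tailed, %s)\n",
              x$df, x$t, x$p, x$tails, x$variance))
  cat(sprintf("95%% CI [%.4f, %.4f], Cohen's d = %.4f\n",
              x$ci95[1], x$ci95[2], x$d))
  invisible(x)
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

# orthonormal columns orthogonal to the constant, for l levels
.within_contrasts <- function(l) stats::contr.poly(l)

# residuals of multiple response columns on a design matrix via one QR
.resid_ss <- function(X, Z) {
  Z <- as.matrix(Z)
  if (is.null(X) || ncol(X) == 0) return(colSums(Z^2))
  colSums(as.matrix(stats::lm.fit(X, Z)$residuals)^2)
}

#' Split-plot mixed ANOVA with Type III sums of squares
#'
#' Univariate split-plot decomposition of a long-format table. Between-
#' subject effects (and an optional between-subject covariate) are tested
#' against the subjects-within-groups error; each within-subject effect and
#' its interactions with between factors are tested against the
#' corresponding subject-by-within residual stratum. Type III sums of
#' squares come from sum-to-zero effect coding and full-versus-reduced model
#' comparison, so unbalanced between groups (e.g. 6:4 sex splits) are
#' handled. Degrees of freedom are reported uncorrected by default;
#' Greenhouse-Geisser adjustment of within-stratum df is available via
#' `sphericity`.
#'
#' @param data Long-format data frame: one row per subject x within-cell.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param between Character vector of between-subject factor columns
#'   (constant within subject).
#' @param within Character vector of within-subject factor columns; every
#'   subject must have every within cell exactly once.
#' @param covariate Optional name of a between-subject numeric covariate
#'   (e.g. a head-size scaling factor); centred and entered in the
#'   between-subject stratum only.
#' @param sphericity `"none"` (default; uncorrected df) or
#'   `"greenhouse-geisser"`.
#' @return Data frame of class `anova_table` with columns `effect`,
#'   `stratum`, `SS`, `df1`, `df2`, `MS`, `F`, `p`, `pes` (partial eta
#'   squared, SS_effect / (SS_effect + SS_error_of_stratum)) and
#'   `SS_error`. The error SS and df of each stratum are attached as the
#'   `strata` attribute.
#' @export
mixed_anova <- function(data, dv, subject, between = character(),
                        within = character(), covariate = NULL,
                        sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  need <- c(dv, subject, between, within, covariate)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("columns not found: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(data[[dv]]))
    stop("missing response values are not allowed", call. = FALSE)
  data[[subject]] <- factor(data[[subject]])
  for (f in c(between, within)) data[[f]] <- factor(data[[f]])
  subj_levels <- levels(data[[subject]])
  n_subj <- length(subj_levels)

  # within-cell layout: first within factor varies fastest
  w_levels <- lapply(within, function(f) levels(data[[f]]))
  names(w_levels) <- within
  m <- prod(vapply(w_levels, length, numeric(1)), 1)
  if (length(within)) {
    cell <- interaction(data[setdiff(within, character(0))], drop = FALSE,
                        lex.order = FALSE)
    grid <- do.call(expand.grid, w_levels)
    cell_order <- interaction(grid, lex.order = FALSE)
    idx <- matrix(NA_integer_, n_subj, m)
    row_of <- split(seq_len(nrow(data)), data[[subject]])
    for (i in seq_len(n_subj)) {
      ri <- row_of[[subj_levels[i]]]
      pos <- match(cell_order, cell[ri])
      if (anyNA(pos) || length(ri) != m)
        stop("incomplete or duplicated within-subject cells for subject ",
             subj_levels[i], call. = FALSE)
      idx[i, ] <- ri[pos]
    }
    Y <- matrix(data[[dv]][as.vector(idx)], n_subj, m)
  } else {
    if (nrow(data) != n_subj)
      stop("without within factors each subject must have exactly one row",
           call. = FALSE)
    ord <- match(subj_levels, data[[subject]])
    Y <- matrix(data[[dv]][ord], n_subj, 1)
    idx <- matrix(ord, n_subj, 1)
  }

  # between-subject design, one row per subject
  subj_rows <- idx[, 1]
  bdat <- data[subj_rows, c(subject, between, covariate), drop = FALSE]
  for (b in between) {
    agg <- tapply(as.character(data[[b]]), data[[subject]],
                  function(v) length(unique(v)))
    if (any(agg > 1))
      stop("between factor '", b, "' varies within subject", call. = FALSE)
  }
  if (!is.null(covariate)) {
    if (!is.numeric(bdat[[covariate]]))
      stop("covariate must be numeric", call. = FALSE)
    bdat[[covariate]] <- bdat[[covariate]] - mean(bdat[[covariate]])
  }
  contr <- lapply(between, function(b) "contr.sum")
  names(contr) <- between
  form_b <- if (length(between))
    stats::reformulate(paste(between, collapse = "*")) else ~ 1
  Xb <- stats::model.matrix(form_b, bdat, contrasts.arg =
                              if (length(between)) contr else NULL)
  b_assign <- attr(Xb, "assign")
  b_labels <- attr(stats::terms(form_b), "term.labels")
  if (qr(Xb)$rank < ncol(Xb))
    stop("rank-deficient between-subject design after effect coding",
         call. = FALSE)
  Xcov <- if (!is.null(covariate)) cbind(Xb, cov = bdat[[covariate]]) else Xb
  if (!is.null(covariate) && qr(Xcov)$rank < ncol(Xcov))
    stop("rank-deficient design with covariate", call. = FALSE)

  # per-within-factor orthonormal contrast blocks (and constant blocks)
  const_block <- lapply(w_levels, function(lv)
    matrix(1 / sqrt(length(lv)), length(lv), 1))
  contr_block <- lapply(w_levels, function(lv) .within_contrasts(length(lv)))

  # strata: all subsets of within factors; empty set = between stratum
  subsets <- list(character(0))
  for (f in within)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))

  rows <- list()
  strata_info <- list()
  # drop one term's columns and return Type III SS summed over Z columns
  ss_drop <- function(X, Z, cols, rss_full) {
    sum(.resid_ss(X[, -cols, drop = FALSE], Z) - rss_full)
  }
  for (S in subsets) {
    blocks <- lapply(within, function(f)
      if (f %in% S) contr_block[[f]] else const_block[[f]])
    M <- Reduce(`%x%`, rev(blocks), right = FALSE)
    if (is.null(M)) M <- matrix(1, 1, 1)
    Z <- Y %*% M
    q <- ncol(Z)
    is_between_stratum <- length(S) == 0
    X <- if (is_between_stratum) Xcov else Xb
    p_cols <- ncol(X)
    fit <- stats::lm.fit(X, Z)
    rss_full <- colSums(as.matrix(fit$residuals)^2)
    ss_err <- sum(rss_full)
    df_err <- q * (n_subj - p_cols)
    if (df_err <= 0)
      stop("no residual degrees of freedom in stratum", call. = FALSE)
    stratum_name <- if (is_between_stratum) "between"
      else paste0("subject:", paste(S, collapse = ":"))
    strata_info[[stratum_name]] <- list(SS_error = ss_err, df_error = df_err)
    eff <- list()
    if (is_between_stratum) {
      for (ti in seq_along(b_labels)) {
        cols <- which(b_assign == ti)
        eff[[b_labels[ti]]] <- list(cols = cols, df = length(cols))
      }
      if (!is.null(covariate))
        eff[[covariate]] <- list(cols = ncol(X), df = 1)
    } else {
      s_label <- paste(S, collapse = ":")
      eff[[s_label]] <- list(cols = which(b_assign == 0), df = q)
      for (ti in seq_along(b_labels)) {
        cols <- which(b_assign == ti)
        eff[[paste(s_label, b_labels[ti], sep = ":")]] <-
          list(cols = cols, df = q * length(cols))
      }
    }
    eps <- NA_real_
    if (sphericity == "greenhouse-geisser" && !is_between_stratum && q > 1) {
      Sigma <- crossprod(as.matrix(fit$residuals)) / (n_subj - p_cols)
      eps <- sum(diag(Sigma))^2 / (q * sum(Sigma^2))
    }
    for (en in names(eff)) {
      e <- eff[[en]]
      ss <- ss_drop(X, Z, e$cols, rss_full)
      df1 <- e$df
      df2 <- df_err
      Fv <- (ss / df1) / (ss_err / df_err)
      adj <- if (!is.na(eps)) eps else 1
      pv <- stats::pf(Fv, df1 * adj, df2 * adj, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = en, stratum = stratum_name, SS = ss, df1 = df1, df2 = df2,
        MS = ss / df1, F = Fv, p = pv, pes = ss / (ss + ss_err),
        SS_error = ss_err, gg_epsilon = eps, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "strata") <- strata_info
  class(out) <- c("anova_table", class(out))
  out
}

#' Write an ANOVA table to CSV
#'
#' @param x An `anova_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_anova_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("effect", "stratum", "SS", "df1",
                                        "df2", "F", "p", "pes")],
                   path, row.names = FALSE)
  invisible(path)
}
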