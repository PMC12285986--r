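# Trial scoring: localisation error, and the resampling-based
# target / misbinding / guessing classification of placement responses.

#' Localisation error
#'
#' Euclidean distance, in pixels, between the placement response and the
#' original target location. Vectorised.
#'
#' @param response_x,response_y,target_x,target_y Coordinates in pixels.
#' @return Nonnegative numeric vector of distances.
#' @export
localisation_error <- function(response_x, response_y, target_x, target_y) {
  if (anyNA(c(response_x, response_y, target_x, target_y)))
    stop("localisation_error: missing coordinates", call. = FALSE)
  sqrt((response_x - target_x)^2 + (response_y - target_y)^2)
}

#' Classify one placement response as target / misbinding / guessing
#'
#' For each resample one pool point (a non-target taken from another trial)
#' is drawn uniformly, and the minimum of (i) distance to the target,
#' (ii) distance to the closest own non-target (3-item trials only) and
#' (iii) distance to the drawn pool point decides the outcome class. Class
#' probabilities are tallies over resamples. In `"exact"` mode the whole pool
#' is enumerated once, which gives the sampling estimator's expectation
#' deterministically and serves as the testing oracle. On 1-item trials only
#' (i) vs (iii) are compared and `p_misbind` is identically 0.
#'
#' Distance ties are broken in favour of the target, then the own
#' non-target; for continuous coordinates these are probability-zero events,
#' the rule matters only for integer fixtures.
#'
#' @param response,target Numeric length-2 coordinates (x, y).
#' @param nontargets Matrix with 2 columns (one row per own non-target), or
#'   `NULL` for 1-item trials.
#' @param pool Matrix with 2 columns: candidate non-targets from the
#'   subject's other trials. Must be non-empty.
#' @param n_resamples Number of resamples in sampling mode (default 5000,
#'   matching the published procedure), or the string `"exact"`.
#' @param seed Integer seed for sampling mode (ignored in exact mode).
#' @return List of class `trial_classification`: `p_target`, `p_misbind`,
#'   `p_guess` (summing to 1), `n_resamples_used` (count or `"exact"`).
#' @export
classify_response <- function(response, target, nontargets = NULL, pool,
                              n_resamples = 5000, seed = NULL) {
  pool <- rbind(pool)
  if (is.null(pool) || nrow(pool) == 0)
    stop("classification undefined: empty pool of other-trial non-targets",
         call. = FALSE)
  d_target <- sqrt(sum((response - target)^2))
  d_own <- if (is.null(nontargets) || NROW(nontargets) == 0) Inf else {
    nt <- rbind(nontargets)
    min(sqrt((response[1] - nt[, 1])^2 + (response[2] - nt[, 2])^2))
  }
  d_pool <- sqrt((response[1] - pool[, 1])^2 + (response[2] - pool[, 2])^2)
  exact <- identical(n_resamples, "exact")
  if (!exact) {
    stopifnot(is.numeric(n_resamples), n_resamples >= 1)
    if (!is.null(seed)) set.seed(seed)
    d_pool <- d_pool[sample.int(length(d_pool), n_resamples, replace = TRUE)]
  }
  is_target <- d_target <= pmin(d_own, d_pool)
  is_misbind <- !is_target & d_own <= d_pool
  n <- length(d_pool)
  structure(list(p_target = sum(is_target) / n,
                 p_misbind = sum(is_misbind) / n,
                 p_guess = sum(!is_target & !is_misbind) / n,
                 n_resamples_used = if (exact) "exact" else n_resamples),
            class = "trial_classification")
}

# own non-target matrix for one trial row (NULL on 1-item trials)
.own_nontargets <- function(trials, i) {
  if (trials$n_items[i] == 1) return(NULL)
  matrix(c(trials$nt1_x[i], trials$nt2_x[i],
           trials$nt1_y[i], trials$nt2_y[i]), ncol = 2)
}

#' Classify every trial of a trial table
#'
#' Applies [classify_response()] per trial. The pool for a trial consists of
#' all non-targets from the *same subject's other* trials (each 3-item trial
#' contributes two); the trial's own non-targets are excluded. Trials on
#' which the wrong shape was identified are excluded from classification
#' (their probabilities are `NA`), but their non-targets still feed the pool.
#'
#' @param trials Trial table as produced by [generate_trials()].
#' @param n_resamples Count or `"exact"` (see [classify_response()]).
#' @param seed Base seed for sampling mode; per-trial streams are derived
#'   from it.
#' @param include_incorrect Classify trials with incorrect identification
#'   too (default `FALSE`, matching the exclusion rule).
#' @return Data frame aligned to `trials` rows: `subject_id`, `condition`,
#'   `p_target`, `p_misbind`, `p_guess`, `n_resamples_used`.
#' @export
classify_trials <- function(trials, n_resamples = 5000, seed = 1,
                            include_incorrect = FALSE) {
  n <- nrow(trials)
  p_t <- p_m <- p_g <- rep(NA_real_, n)
  for (sid in unique(trials$subject_id)) {
    idx <- which(trials$subject_id == sid)
    sub <- trials[idx, , drop = FALSE]
    has_nt <- which(sub$n_items == 3)
    pool_all <- cbind(c(sub$nt1_x[has_nt], sub$nt2_x[has_nt]),
                      c(sub$nt1_y[has_nt], sub$nt2_y[has_nt]))
    pool_trial <- rep(has_nt, 2L)  # source trial of each pool row
    if (nrow(pool_all) == 0)
      stop("classification undefined for subject ", sid,
           ": no 3-item trials to build a non-target pool from",
           call. = FALSE)
    for (j in seq_len(nrow(sub))) {
      if (!include_incorrect && !sub$identified_correctly[j]) next
      pool <- pool_all[pool_trial != j, , drop = FALSE]
      cl <- classify_response(
        response = c(sub$response_x[j], sub$response_y[j]),
        target = c(sub$target_x[j], sub$target_y[j]),
        nontargets = .own_nontargets(sub, j),
        pool = pool, n_resamples = n_resamples,
        seed = if (identical(n_resamples, "exact")) NULL
               else (as.numeric(seed) * 7919 + idx[j]) %% 2147483629)
      p_t[idx[j]] <- cl$p_target
      p_m[idx[j]] <- cl$p_misbind
      p_g[idx[j]] <- cl$p_guess
    }
  }
  data.frame(subject_id = trials$subject_id, condition = trials$condition,
             p_target = p_t, p_misbind = p_m, p_guess = p_g,
             n_resamples_used = if (identical(n_resamples, "exact"))
               "exact" else as.character(n_resamples),
             stringsAsFactors = FALSE)
}

#' Summarise trials per subject and condition
#'
#' Identification accuracy is computed over all trials of a condition;
#' localisation error, response time and the classified guessing/misbinding
#' probabilities are averaged only over identified-correct trials (the
#' exclusion rule). Misbinding summaries exist only for 3-item conditions.
#' A condition with zero identified-correct trials yields `NA` localisation
#' summaries and is flagged via `all_excluded`, never zero-filled.
#'
#' @param trials Trial table.
#' @param classifications Output of [classify_trials()], row-aligned to
#'   `trials`; may be `NULL` to skip the probability summaries.
#' @return Data frame with columns `subject_id`, `n_items`, `delay_s`,
#'   `condition`, `ident_acc`, `avg_error_px`, `rt_s`, `guess_rate`,
#'   `misbind_rate`, `n_trials_included`, `all_excluded`.
#' @export
summarise_conditions <- function(trials, classifications = NULL) {
  if (!is.null(classifications) && nrow(classifications) != nrow(trials))
    stop("classifications must be row-aligned to trials", call. = FALSE)
  err <- localisation_error(trials$response_x, trials$response_y,
                            trials$target_x, trials$target_y)
  key <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    i <- which(key == k)
    inc <- i[trials$identified_correctly[i]]
    three_item <- trials$n_items[i[1]] == 3
    data.frame(
      subject_id = trials$subject_id[i[1]],
      n_items = trials$n_items[i[1]],
      delay_s = trials$delay_s[i[1]],
      condition = trials$condition[i[1]],
      ident_acc = length(inc) / length(i),
      avg_error_px = if (length(inc)) mean(err[inc]) else NA_real_,
      rt_s = if (length(inc)) mean(trials$response_time_s[inc]) else NA_real_,
      guess_rate = if (length(inc) && !is.null(classifications))
        mean(classifications$p_guess[inc]) else NA_real_,
      misbind_rate = if (three_item && length(inc) &&
                         !is.null(classifications))
        mean(classifications$p_misbind[inc]) else NA_real_,
      n_trials_included = length(inc),
      all_excluded = length(inc) == 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$n_items, out$delay_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
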