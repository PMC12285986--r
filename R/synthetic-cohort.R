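# Synthetic cohort generation: subjects, object-location trials, volume tables.

#' Screen geometry of the touch display
#'
#' The object-location task is administered on a tablet touch screen addressed
#' as a pixel matrix. Coordinates are continuous, origin top-left,
#' `x` in `[0, width_px)`, `y` in `[0, height_px)`.
#'
#' @param width_px,height_px Positive screen dimensions in pixels. Defaults
#'   are the 1536 x 2048 tablet matrix used by the task.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1536, height_px = 2048) {
  stopifnot(is.numeric(width_px), is.numeric(height_px),
            width_px > 0, height_px > 0)
  structure(list(width_px = width_px, height_px = height_px),
            class = "screen_geometry")
}

#' Response-mixture parameters for one task condition
#'
#' Placement responses are generated from a three-component mixture: with
#' probability `p_target` a Gaussian displacement around the target, with
#' `p_misbind` the same Gaussian around a uniformly chosen non-target
#' (binding error), with `p_guess` a uniform point on the screen
#' (no location information).
#'
#' @param p_target,p_misbind,p_guess Mixture weights; must sum to 1 (within
#'   1e-12). `p_misbind` must be 0 for 1-item conditions.
#' @param sigma_px Isotropic Gaussian placement noise, pixels (> 0).
#' @param ident_accuracy Probability of identifying the correct shape out of
#'   two at test.
#' @param rt_mean_s,rt_sd_s Mean and sd of the positive-truncated Gaussian
#'   response-time distribution, seconds.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(p_target, p_misbind, p_guess, sigma_px,
                           ident_accuracy = 0.9,
                           rt_mean_s = 2, rt_sd_s = 0.5) {
  w <- c(p_target, p_misbind, p_guess)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  stopifnot(sigma_px > 0, ident_accuracy >= 0, ident_accuracy <= 1,
            rt_mean_s > 0, rt_sd_s > 0)
  structure(list(p_target = p_target, p_misbind = p_misbind,
                 p_guess = p_guess, sigma_px = sigma_px,
                 ident_accuracy = ident_accuracy,
                 rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s),
            class = "mixture_params")
}

#' Condition key
#'
#' Canonical string key for a task condition, e.g. `"3item_1s"`.
#'
#' @param n_items Number of shapes shown (1 or 3).
#' @param delay_s Retention delay in seconds (1 or 4).
#' @return Character key.
#' @export
condition_key <- function(n_items, delay_s) {
  sprintf("%ditem_%ds", n_items, delay_s)
}

#' Task configuration
#'
#' The default layout is the published task: four conditions crossing 1 or 3
#' shapes with 1 or 4 s delay, 30 trials per condition equally distributed
#' across 3 blocks (120 trials).
#'
#' @param conditions Data frame with columns `n_items` and `delay_s`.
#' @param trials_per_condition Trials per condition; must be divisible by
#'   `blocks`.
#' @param blocks Number of blocks.
#' @param screen A [screen_geometry()].
#' @param min_item_separation_px Minimum pairwise distance between
#'   simultaneously presented shapes (and between response-relevant item
#'   locations), pixels. Keeps the classifier well-posed.
#' @return An object of class `task_config`.
#' @export
task_config <- function(conditions = data.frame(n_items = c(1, 1, 3, 3),
                                                delay_s = c(1, 4, 1, 4)),
                        trials_per_condition = 30,
                        blocks = 3,
                        screen = screen_geometry(),
                        min_item_separation_px = 200) {
  stopifnot(is.data.frame(conditions),
            all(c("n_items", "delay_s") %in% names(conditions)),
            all(conditions$n_items %in% c(1, 3)),
            trials_per_condition > 0, blocks > 0,
            min_item_separation_px >= 0)
  if (trials_per_condition %% blocks != 0)
    stop("trials_per_condition must be divisible by blocks", call. = FALSE)
  structure(list(conditions = conditions,
                 trials_per_condition = trials_per_condition,
                 blocks = blocks, screen = screen,
                 min_item_separation_px = min_item_separation_px),
            class = "task_config")
}

#' Default condition-wise mixture parameters
#'
#' Study-like defaults: single-item trials are mostly on-target with a small
#' guessing rate and no misbinding (no non-target exists); three-item trials
#' carry a substantial misbinding component and a higher guessing rate, and
#' the longer delay degrades precision and identification slightly.
#'
#' @return Named list of [mixture_params()], keyed by [condition_key()].
#' @export
default_mixture_params <- function() {
  list(
    "1item_1s" = mixture_params(0.92, 0, 0.08, sigma_px = 55,
                                ident_accuracy = 0.95),
    "1item_4s" = mixture_params(0.88, 0, 0.12, sigma_px = 65,
                                ident_accuracy = 0.93),
    "3item_1s" = mixture_params(0.68, 0.18, 0.14, sigma_px = 85,
                                ident_accuracy = 0.88),
    "3item_4s" = mixture_params(0.62, 0.22, 0.16, sigma_px = 95,
                                ident_accuracy = 0.85)
  )
}

#' Default group specification for subject generation
#'
#' One pool shaped like the study sample: n subjects, VVIQ mean 62.23
#' (sd 12.53), ages 54-80 around mean 68 (sd 7.2), 29:24 female:male ratio.
#'
#' @param n Cohort size.
#' @return Named list of group specifications.
#' @export
default_group_spec <- function(n = 53) {
  list(sample = list(size = n, vviq_mean = 62.23, vviq_sd = 12.53,
                     female_ratio = 29 / 53,
                     age_mean = 68, age_sd = 7.2,
                     age_range = c(54, 80)))
}

# draw a rounded Gaussian clipped to a closed range
.rnorm_clipped_int <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd))))
}

#' Generate a subject table
#'
#' @param n Total number of subjects (must equal the sum of group sizes).
#' @param group_spec Named list of groups; each element is a list with
#'   `size`, `vviq_mean`, `vviq_sd`, `female_ratio`, `age_mean`, `age_sd`
#'   and optionally `age_range` (default c(40, 90)).
#' @param plant_extremes If `TRUE`, the lowest-VVIQ subject is set to the
#'   scale minimum (16; role `"aphant"`) and the highest to the maximum
#'   (80; role `"hphant"`).
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @return Data frame with columns `subject_id`, `group`, `age_years`, `sex`,
#'   `vviq_total`, `scaling_factor`, `role`.
#' @details VVIQ totals are rounded Gaussians clipped to the scale range
#'   `[16, 80]`; item-level generation is out of scope. The per-subject
#'   scaling factor emulates a head-size normalisation scalar
#'   (positive, around 1.25).
#' @export
generate_subjects <- function(n = 53, group_spec = default_group_spec(n),
                              plant_extremes = TRUE, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive count", call. = FALSE)
  if (!is.list(group_spec) || length(group_spec) == 0)
    stop("group_spec must be a non-empty named list of groups", call. = FALSE)
  sizes <- vapply(group_spec, function(g) g$size, numeric(1))
  if (sum(sizes) > n)
    stop("group sizes exceed n", call. = FALSE)
  if (sum(sizes) != n)
    stop("group sizes must sum to n", call. = FALSE)
  if (plant_extremes && n < 2)
    stop("plant_extremes requires at least 2 subjects", call. = FALSE)
  set.seed(seed)
  rows <- lapply(names(group_spec), function(gname) {
    g <- group_spec[[gname]]
    m <- g$size
    rng <- if (is.null(g$age_range)) c(40, 90) else g$age_range
    n_f <- round(m * g$female_ratio)
    sex <- sample(c(rep("female", n_f), rep("male", m - n_f)))
    data.frame(
      group = gname,
      age_years = .rnorm_clipped_int(m, g$age_mean, g$age_sd, rng[1], rng[2]),
      sex = sex,
      vviq_total = .rnorm_clipped_int(m, g$vviq_mean, g$vviq_sd, 16, 80),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("S%03d", seq_len(n))
  out$scaling_factor <- abs(stats::rnorm(n, 1.25, 0.08))
  out$role <- "none"
  if (plant_extremes) {
    i_lo <- which.min(out$vviq_total)
    i_hi <- which.max(out$vviq_total)
    if (i_lo == i_hi) i_hi <- setdiff(seq_len(n), i_lo)[1]
    out$vviq_total[i_lo] <- 16L
    out$vviq_total[i_hi] <- 80L
    out$role[i_lo] <- "aphant"
    out$role[i_hi] <- "hphant"
  }
  out <- out[, c("subject_id", "group", "age_years", "sex", "vviq_total",
                 "scaling_factor", "role")]
  rownames(out) <- NULL
  out
}

# uniform points on the screen subject to a minimum pairwise separation,
# by joint rejection (edge truncation by resampling, never clipping)
.place_items <- function(k, screen, min_sep) {
  repeat {
    x <- stats::runif(k, 0, screen$width_px)
    y <- stats::runif(k, 0, screen$height_px)
    if (k == 1 || min(stats::dist(cbind(x, y))) >= min_sep)
      return(cbind(x = x, y = y))
  }
}

# Gaussian displacement around a centre, resampled until on screen
.gaussian_on_screen <- function(centre, sigma, screen) {
  repeat {
    p <- centre + stats::rnorm(2, 0, sigma)
    if (p[1] >= 0 && p[1] < screen$width_px &&
        p[2] >= 0 && p[2] < screen$height_px)
      return(p)
  }
}

.positive_truncated_normal <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Generate trial-level task data for one subject
#'
#' Draws item layouts uniformly on the screen (subject to the minimum
#' separation), then a placement response from the condition's mixture:
#' target-anchored Gaussian, non-target-anchored Gaussian (misbinding), or
#' uniform guess. Identification correctness is Bernoulli and response time a
#' positive-truncated Gaussian.
#'
#' @param subject_id Identifier copied into every row.
#' @param params_by_condition Named list of [mixture_params()], keyed by
#'   [condition_key()]; every condition in `task` must be present and 1-item
#'   conditions must have `p_misbind = 0`.
#' @param task A [task_config()].
#' @param seed Integer seed.
#' @return Data frame with one row per trial: `subject_id`, `block`,
#'   `trial`, `n_items`, `delay_s`, `condition`, `target_x`, `target_y`,
#'   `nt1_x`, `nt1_y`, `nt2_x`, `nt2_y` (NA on 1-item trials),
#'   `identified_correctly`, `response_x`, `response_y`, `response_time_s`.
#' @export
generate_trials <- function(subject_id, params_by_condition = default_mixture_params(),
                            task = task_config(), seed = 1) {
  keys <- condition_key(task$conditions$n_items, task$conditions$delay_s)
  missing <- setdiff(keys, names(params_by_condition))
  if (length(missing))
    stop("missing mixture parameters for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (i in seq_along(keys)) {
    p <- params_by_condition[[keys[i]]]
    if (task$conditions$n_items[i] == 1 && p$p_misbind > 0)
      stop("p_misbind must be 0 for 1-item condition ", keys[i],
           call. = FALSE)
  }
  set.seed(seed)
  scr <- task$screen
  per_block <- task$trials_per_condition / task$blocks
  rows <- vector("list", length(keys) * task$trials_per_condition)
  r <- 0L
  for (i in seq_along(keys)) {
    ni <- task$conditions$n_items[i]
    dl <- task$conditions$delay_s[i]
    p <- params_by_condition[[keys[i]]]
    for (tr in seq_len(task$trials_per_condition)) {
      items <- .place_items(ni, scr, task$min_item_separation_px)
      target <- items[1, ]
      comp <- sample(c("target", "misbind", "guess"), 1,
                     prob = c(p$p_target, p$p_misbind, p$p_guess))
      resp <- switch(comp,
        target = .gaussian_on_screen(target, p$sigma_px, scr),
        misbind = .gaussian_on_screen(items[1 + sample(ni - 1, 1), ],
                                      p$sigma_px, scr),
        guess = c(stats::runif(1, 0, scr$width_px),
                  stats::runif(1, 0, scr$height_px)))
      r <- r + 1L
      rows[[r]] <- data.frame(
        subject_id = subject_id,
        block = ((tr - 1L) %/% per_block) + 1L,
        trial = tr,
        n_items = ni, delay_s = dl, condition = keys[i],
        target_x = target[1], target_y = target[2],
        nt1_x = if (ni == 3) items[2, 1] else NA_real_,
        nt1_y = if (ni == 3) items[2, 2] else NA_real_,
        nt2_x = if (ni == 3) items[3, 1] else NA_real_,
        nt2_y = if (ni == 3) items[3, 2] else NA_real_,
        identified_correctly = stats::runif(1) < p$ident_accuracy,
        response_x = resp[1], response_y = resp[2],
        response_time_s = .positive_truncated_normal(1, p$rt_mean_s, p$rt_sd_s),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate trials for a whole cohort
#'
#' Calls [generate_trials()] once per subject with a per-subject seed derived
#' from `seed`. `params_by_condition` may be a function of the subject row,
#' so simulations can plant subject-dependent performance (e.g. mixture
#' weights that depend on VVIQ).
#'
#' @param subjects Subject table from [generate_subjects()].
#' @param params_by_condition Named list of [mixture_params()] (as in
#'   [generate_trials()]), or a function taking one subject row (a one-row
#'   data frame) and returning such a list.
#' @inheritParams generate_trials
#' @return Row-bound trial table for all subjects.
#' @export
generate_cohort_trials <- function(subjects,
                                   params_by_condition = default_mixture_params(),
                                   task = task_config(), seed = 1) {
  out <- lapply(seq_len(nrow(subjects)), function(i) {
    params <- if (is.function(params_by_condition))
      params_by_condition(subjects[i, , drop = FALSE]) else params_by_condition
    generate_trials(subjects$subject_id[i], params, task,
                    seed = (as.numeric(seed) * 1009 + i) %% 2147483629)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Default regional volume catalogue
#'
#' The 57-volume catalogue: Set A, 11 volumes of four relatively large
#' imagery-implicated areas (hippocampus, whole hippocampus, area V1,
#' fusiform gyrus); Set B, 36 hippocampal subfield volumes (12 subfields by
#' left/right/bilateral); Set C, 3 amygdala volumes (control); Set D, 7 motor
#' volumes (control). `sides` is `"LRB"` where a bilateral column exists and
#' `"LR"` otherwise; bilateral volumes are always left + right.
#'
#' @return Data frame with columns `region`, `set_label`, `sides`,
#'   `baseline_mm3`, `sd_mm3`.
#' @export
default_region_catalogue <- function() {
  cat_row <- function(region, set_label, sides, baseline, sd)
    data.frame(region = region, set_label = set_label, sides = sides,
               baseline_mm3 = baseline, sd_mm3 = sd,
               stringsAsFactors = FALSE)
  rbind(
    cat_row("hippocampus",         "A", "LRB", 3800, 380),
    cat_row("whole_hippocampus",   "A", "LR",  3400, 340),
    cat_row("V1",                  "A", "LRB", 5000, 500),
    cat_row("fusiform_gyrus",      "A", "LRB", 9500, 950),
    cat_row("parasubiculum",       "B", "LRB",   62,  12),
    cat_row("presubiculum",        "B", "LRB",  300,  30),
    cat_row("subiculum",           "B", "LRB",  440,  44),
    cat_row("CA1",                 "B", "LRB",  640,  64),
    cat_row("CA3",                 "B", "LRB",  210,  21),
    cat_row("CA4",                 "B", "LRB",  250,  25),
    cat_row("GC_ML_DG",            "B", "LRB",  290,  29),
    cat_row("HATA",                "B", "LRB",   60,  10),
    cat_row("fimbria",             "B", "LRB",   60,  15),
    cat_row("molecular_layer",     "B", "LRB",  560,  56),
    cat_row("hippocampal_fissure", "B", "LRB",  160,  20),
    cat_row("hippocampal_tail",    "B", "LRB",  550,  55),
    cat_row("amygdala",            "C", "LRB", 1310, 130),
    cat_row("BA4a",                "D", "LR",  2600, 260),
    cat_row("BA4p",                "D", "LR",  2200, 220),
    cat_row("B4",                  "D", "LRB", 4800, 480)
  )
}

#' Volume effect specification
#'
#' Defines the multiplicative structure of the synthetic volume table. The
#' VVIQ-group multiplier applies only to imagery-implicated Sets A and B
#' (control Sets C and D receive exactly 1), for subjects labelled
#' `vviq_group == "high"`. The sex multiplier applies to males in all sets
#' (a nuisance effect, not the contrast of interest). Planted single-case
#' multipliers apply to the `aphant`/`hphant` roles in Sets A and B.
#'
#' @param region_catalogue Data frame as in [default_region_catalogue()].
#' @param vviq_group_multiplier Expected High/Low volume ratio in Sets A/B
#'   (default 1.10, i.e. about a 10 percent group effect).
#' @param sex_multiplier Male/female ratio (default 1.05).
#' @param planted_case_multipliers Named numeric, multipliers for roles
#'   `aphant` and `hphant` (defaults 0.80 and 1.20).
#' @return An object of class `volume_effect_spec`.
#' @export
volume_effect_spec <- function(region_catalogue = default_region_catalogue(),
                               vviq_group_multiplier = 1.10,
                               sex_multiplier = 1.05,
                               planted_case_multipliers = c(aphant = 0.80,
                                                            hphant = 1.20)) {
  if (!nrow(region_catalogue))
    stop("region catalogue must be non-empty", call. = FALSE)
  bad <- setdiff(unique(region_catalogue$set_label), c("A", "B", "C", "D"))
  if (length(bad))
    stop("unknown set label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(vviq_group_multiplier > 0, sex_multiplier > 0,
            all(planted_case_multipliers > 0))
  structure(list(region_catalogue = region_catalogue,
                 vviq_group_multiplier = vviq_group_multiplier,
                 sex_multiplier = sex_multiplier,
                 planted_case_multipliers = planted_case_multipliers),
            class = "volume_effect_spec")
}

#' Generate a regional volume table
#'
#' One record per subject x region x available side. Left and right volumes
#' are independent truncated-positive Gaussians around
#' baseline x applicable multipliers; bilateral volumes are exactly
#' left + right where a bilateral column exists.
#'
#' @param subjects Subject table; the optional columns `vviq_group`
#'   (`"high"`/`"low"`, e.g. attached by [attach_group_labels()]) and `role`
#'   (`"aphant"`/`"hphant"`) switch on the planted effects.
#' @param spec A [volume_effect_spec()].
#' @param seed Integer seed.
#' @return Long data frame: `subject_id`, `region`, `side`
#'   (left/right/bilateral), `set_label`, `volume_mm3`.
#' @export
generate_volumes <- function(subjects, spec = volume_effect_spec(), seed = 1) {
  cat <- spec$region_catalogue
  bad <- setdiff(unique(cat$set_label), c("A", "B", "C", "D"))
  if (length(bad))
    stop("unknown set label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  vviq_group <- if ("vviq_group" %in% names(subjects))
    as.character(subjects$vviq_group) else rep("none", nrow(subjects))
  role <- if ("role" %in% names(subjects))
    as.character(subjects$role) else rep("none", nrow(subjects))
  out <- vector("list", nrow(subjects) * nrow(cat))
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    mult_sex <- if (subjects$sex[i] == "male") spec$sex_multiplier else 1
    for (j in seq_len(nrow(cat))) {
      in_active <- cat$set_label[j] %in% c("A", "B")
      mult <- mult_sex
      if (in_active) {
        if (identical(vviq_group[i], "high"))
          mult <- mult * spec$vviq_group_multiplier
        if (role[i] %in% names(spec$planted_case_multipliers))
          mult <- mult * spec$planted_case_multipliers[[role[i]]]
      }
      has <- c(left = grepl("L", cat$sides[j], fixed = TRUE),
               right = grepl("R", cat$sides[j], fixed = TRUE),
               bilateral = grepl("B", cat$sides[j], fixed = TRUE))
      if (has["bilateral"] && !(has["left"] && has["right"]))
        stop("bilateral volume requires both left and right sides (region ",
             cat$region[j], ")", call. = FALSE)
      lr <- .positive_truncated_normal(sum(has[c("left", "right")]),
                                       cat$baseline_mm3[j] * mult,
                                       cat$sd_mm3[j])
      sides <- c("left", "right")[has[c("left", "right")]]
      vols <- lr
      if (has["bilateral"]) {
        sides <- c(sides, "bilateral")
        vols <- c(vols, sum(lr))
      }
      k <- k + 1L
      out[[k]] <- data.frame(subject_id = subjects$subject_id[i],
                             region = cat$region[j], side = sides,
                             set_label = cat$set_label[j],
                             volume_mm3 = vols, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out[seq_len(k)])
  rownames(out) <- NULL
  out
}
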