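# End-to-end orchestration: table I/O with validation, analysis
# configuration, and the full simulate/load -> score -> design -> test run.

.trial_cols <- c("subject_id", "block", "trial", "n_items", "delay_s",
                 "condition", "target_x", "target_y", "nt1_x", "nt1_y",
                 "nt2_x", "nt2_y", "identified_correctly", "response_x",
                 "response_y", "response_time_s")
.subject_cols <- c("subject_id", "age_years", "sex", "vviq_total",
                   "scaling_factor")
.volume_cols <- c("subject_id", "region", "side", "set_label", "volume_mm3")

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read and validate a subject table
#'
#' @param path CSV file with columns `subject_id`, `age_years`, `sex`,
#'   `vviq_total`, `scaling_factor` (and optionally `group`, `role`).
#' @return Validated data frame.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, .subject_cols, "subject table")
  bad <- which(df$vviq_total < 16 | df$vviq_total > 80 |
                 df$vviq_total != round(df$vviq_total))
  if (length(bad))
    stop("subject table row(s) ", paste(bad, collapse = ", "),
         ": vviq_total outside the 16-80 scale", call. = FALSE)
  bad <- which(df$age_years < 0)
  if (length(bad))
    stop("subject table row(s) ", paste(bad, collapse = ", "),
         ": negative age", call. = FALSE)
  bad <- which(!df$sex %in% c("female", "male"))
  if (length(bad))
    stop("subject table row(s) ", paste(bad, collapse = ", "),
         ": sex must be 'female' or 'male'", call. = FALSE)
  df
}

#' Read and validate a trial table
#'
#' @param path CSV of trial records (the columns written by
#'   [write_cohort()]).
#' @param screen [screen_geometry()] used for the bounds check.
#' @param coords Action when coordinates fall outside the screen:
#'   `"warn"` (default), `"error"` or `"ignore"`.
#' @return Validated data frame.
#' @export
read_trial_table <- function(path, screen = screen_geometry(),
                             coords = c("warn", "error", "ignore")) {
  coords <- match.arg(coords)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, .trial_cols, "trial table")
  num <- c("target_x", "target_y", "response_x", "response_y")
  for (cc in num) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad))
      stop("trial table row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           ": non-numeric ", cc, call. = FALSE)
  }
  bad <- which(df$response_x < 0 | df$response_x >= screen$width_px |
                 df$response_y < 0 | df$response_y >= screen$height_px)
  if (length(bad) && coords != "ignore") {
    msg <- paste0("trial table row(s) ",
                  paste(utils::head(bad, 5), collapse = ", "),
                  ": coordinates outside the screen")
    if (coords == "error") stop(msg, call. = FALSE) else warning(msg,
                                                                 call. = FALSE)
  }
  one_item_with_nt <- which(df$n_items == 1 & !is.na(df$nt1_x))
  if (length(one_item_with_nt))
    stop("trial table row(s) ",
         paste(utils::head(one_item_with_nt, 5), collapse = ", "),
         ": non-targets present on 1-item trials", call. = FALSE)
  df$identified_correctly <- as.logical(df$identified_correctly)
  df
}

#' Read and validate a volume table
#'
#' @param path CSV with columns `subject_id`, `region`, `side`,
#'   `set_label`, `volume_mm3`.
#' @return Validated data frame.
#' @export
read_volume_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, .volume_cols, "volume table")
  bad <- which(!df$set_label %in% c("A", "B", "C", "D"))
  if (length(bad))
    stop("volume table row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": unknown set label", call. = FALSE)
  bad <- which(!df$side %in% c("left", "right", "bilateral"))
  if (length(bad))
    stop("volume table row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": side must be left/right/bilateral", call. = FALSE)
  df
}

#' Write a cohort to CSV files
#'
#' Writes `subjects.csv`, `trials.csv`, `volumes.csv` under `dir`.
#'
#' @param subjects,trials,volumes Cohort tables.
#' @param dir Output directory (created if absent).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort <- function(subjects, trials, volumes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             trials = file.path(dir, "trials.csv"),
             volumes = file.path(dir, "volumes.csv"))
  utils::write.csv(subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(trials, paths["trials"], row.names = FALSE)
  utils::write.csv(volumes, paths["volumes"], row.names = FALSE)
  invisible(paths)
}

#' Analysis configuration
#'
#' Collects every knob of the full analysis with an explicit seed for every
#' stochastic stage (all derived deterministically from `seed`).
#'
#' @param seed Master integer seed.
#' @param n_subjects Cohort size for simulation.
#' @param group_spec,task,mixture_params,volume_spec Generator settings; see
#'   [generate_subjects()], [task_config()], [default_mixture_params()],
#'   [volume_effect_spec()].
#' @param k Extreme-group size.
#' @param n_resamples Classifier resamples, or `"exact"` (default: the
#'   deterministic enumeration, the sampling estimator's expectation).
#' @param single_case_iters Monte-Carlo iterations per single-case test.
#' @param tails Tails for the per-region t-tests (logged in the report).
#' @param percent_denominator Denominator convention for percent
#'   differences.
#' @param alpha Significance threshold used when counting per-region
#'   "significant" differences (uncorrected).
#' @param paths Optional named list (`subjects`, `trials`, `volumes`) of CSV
#'   paths to load instead of simulating.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1, n_subjects = 53,
                            group_spec = default_group_spec(n_subjects),
                            task = task_config(),
                            mixture_params = default_mixture_params(),
                            volume_spec = volume_effect_spec(),
                            k = 10, n_resamples = "exact",
                            single_case_iters = 2e4, tails = 2,
                            percent_denominator = "reference",
                            alpha = 0.05, paths = NULL) {
  stage_seed <- function(i) (as.numeric(seed) * 131071 + i * 8191) %% 2147483629
  structure(list(seed = seed,
                 seeds = list(subjects = stage_seed(1L),
                              trials = stage_seed(2L),
                              volumes = stage_seed(3L),
                              classify = stage_seed(4L),
                              single_case = stage_seed(5L)),
                 n_subjects = n_subjects, group_spec = group_spec,
                 task = task, mixture_params = mixture_params,
                 volume_spec = volume_spec, k = k,
                 n_resamples = n_resamples,
                 single_case_iters = single_case_iters, tails = tails,
                 percent_denominator = percent_denominator, alpha = alpha,
                 paths = paths),
            class = "analysis_config")
}

# wide subject x (region|side) matrix of volumes
.volumes_wide <- function(volumes) {
  key <- paste(volumes$region, volumes$side, sep = "|")
  tab <- stats::xtabs(volume_mm3 ~ subject_id + key, data =
                        cbind(volumes, key = key))
  m <- matrix(tab, nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

# long table of one summary measure for the subjects given, with labels
.measure_long <- function(summaries, subjects, measure, conditions = NULL) {
  df <- summaries
  if (!is.null(conditions)) df <- df[df$condition %in% conditions, ]
  df <- df[, c("subject_id", "condition", measure)]
  names(df)[3] <- "value"
  add <- c("sex", "scaling_factor",
           intersect(c("vviq_group", "age_group"), names(subjects)))
  df <- merge(df, subjects[, c("subject_id", add)], by = "subject_id")
  df[!is.na(df$value), , drop = FALSE]
}

# drop subjects that lost any within cell (zero identified-correct trials)
.complete_subjects <- function(long, n_cells) {
  cnt <- table(long$subject_id)
  keep <- names(cnt)[cnt == n_cells]
  long[long$subject_id %in% keep, , drop = FALSE]
}

.vstm_group_anova <- function(summaries, subjects, measure, conditions,
                              between, covariate = NULL) {
  long <- .measure_long(summaries, subjects, measure, conditions)
  if (length(between) == 1 && between == "vviq_group")
    long <- long[long$vviq_group %in% c("low", "high"), ]
  if (length(between) == 1 && between == "age_group")
    long <- long[long$age_group %in% c("younger", "older"), ]
  long <- .complete_subjects(long, length(conditions))
  mixed_anova(long, dv = "value", subject = "subject_id",
              between = between, within = "condition",
              covariate = covariate)
}

#' Run the full analysis
#'
#' Executes, in order: cohort simulation (or loading), trial classification
#' and scoring, extreme-group selection on VVIQ and age, the VSTM
#' group/gender/age split-plot ANOVAs with Fisher combination of the three
#' VVIQ-group outcomes, per-Set volume ANOVAs (Sets A, B, D four-way; Set C
#' three-way), per-region t-tests, single-case comparisons for the
#' aphantasic and hyperphantasic individuals, the active-versus-control 2x2
#' chi-squared, and the sign-consistency and five-category ordering tests.
#' Deterministic given the config's seed.
#'
#' @param config An [analysis_config()].
#' @return List of class `report_bundle`; see Details.
#' @details Components: `subjects`, `group_assignment`, `age_assignment`,
#'   `vstm_summaries`, `vstm_group_summary` (group means per measure with
#'   percent differences), `vstm_anovas`, `fisher_combined`,
#'   `volume_anovas`, `region_tests`, `single_case`,
#'   `aphant_hphant_paired`, `chi2_active_control`, `sign_consistency`,
#'   `ordering`, `manifest`.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- inputs -------------------------------------------------------------
  if (is.null(config$paths)) {
    subjects <- stage("simulate-subjects",
      generate_subjects(config$n_subjects, config$group_spec,
                        plant_extremes = TRUE,
                        seed = config$seeds$subjects))
    subjects <- attach_group_labels(subjects, k = config$k)
    subjects <- attach_group_labels(subjects, k = config$k,
                                    score_field = "age_years",
                                    labels = c("younger", "older"),
                                    column = "age_group")
    trials <- stage("simulate-trials",
      generate_cohort_trials(subjects, config$mixture_params, config$task,
                             seed = config$seeds$trials))
    volumes <- stage("simulate-volumes",
      generate_volumes(subjects, config$volume_spec,
                       seed = config$seeds$volumes))
  } else {
    subjects <- stage("load-subjects", read_subject_table(config$paths$subjects))
    trials <- stage("load-trials",
                    read_trial_table(config$paths$trials,
                                     screen = config$task$screen))
    volumes <- stage("load-volumes", read_volume_table(config$paths$volumes))
    subjects <- attach_group_labels(subjects, k = config$k)
    subjects <- attach_group_labels(subjects, k = config$k,
                                    score_field = "age_years",
                                    labels = c("younger", "older"),
                                    column = "age_group")
  }
  ga_vviq <- select_extreme_groups(subjects, k = config$k)
  ga_age <- select_extreme_groups(subjects, k = config$k,
                                  score_field = "age_years",
                                  labels = c("younger", "older"))
  # --- scoring ------------------------------------------------------------
  classifications <- stage("classify",
    classify_trials(trials, n_resamples = config$n_resamples,
                    seed = config$seeds$classify))
  summaries <- stage("summarise", summarise_conditions(trials, classifications))

  # --- VSTM ANOVAs --------------------------------------------------------
  all_cond <- condition_key(config$task$conditions$n_items,
                            config$task$conditions$delay_s)
  cond3 <- all_cond[config$task$conditions$n_items == 3]
  vstm_anovas <- list(
    error_group = .vstm_group_anova(summaries, subjects, "avg_error_px",
                                    all_cond, "vviq_group"),
    guess_group = .vstm_group_anova(summaries, subjects, "guess_rate",
                                    all_cond, "vviq_group"),
    misbind_group = .vstm_group_anova(summaries, subjects, "misbind_rate",
                                      cond3, "vviq_group"),
    error_gender = .vstm_group_anova(summaries, subjects, "avg_error_px",
                                     all_cond, "sex",
                                     covariate = "scaling_factor"),
    error_age = .vstm_group_anova(summaries, subjects, "avg_error_px",
                                  all_cond, "age_group")
  )
  group_p <- vapply(vstm_anovas[c("error_group", "guess_group",
                                  "misbind_group")],
                    function(a) a$p[a$effect == "vviq_group"], numeric(1))
  fisher_combined <- fishers_method(group_p)

  # group means and percent differences for the three headline measures
  lab <- subjects$vviq_group[match(summaries$subject_id,
                                   subjects$subject_id)]
  grp_mean <- function(measure, conds, group) {
    v <- summaries[[measure]][lab == group &
                                summaries$condition %in% conds]
    mean(v, na.rm = TRUE)
  }
  vstm_group_summary <- do.call(rbind, lapply(
    list(c("avg_error_px", "all"), c("guess_rate", "all"),
         c("misbind_rate", "three")), function(ms) {
      conds <- if (ms[2] == "all") all_cond else cond3
      hi <- grp_mean(ms[1], conds, "high")
      lo <- grp_mean(ms[1], conds, "low")
      pd <- percent_difference(hi, lo, config$percent_denominator)
      data.frame(measure = ms[1], high_mean = hi, low_mean = lo,
                 percent_difference = pd$percent,
                 denominator = pd$denominator, stringsAsFactors = FALSE)
    }))

  # --- volume ANOVAs per set ---------------------------------------------
  vol <- merge(volumes, subjects[, c("subject_id", "sex", "vviq_group")],
               by = "subject_id")
  vg <- vol[vol$vviq_group %in% c("low", "high"), ]
  lrb_regions <- function(set) unique(vg$region[vg$set_label == set &
                                                  vg$side == "bilateral"])
  set_data <- list(
    A = vg[vg$set_label == "A" & vg$region %in% lrb_regions("A"), ],
    B = vg[vg$set_label == "B", ],
    C = vg[vg$set_label == "C", ],
    D = vg[vg$set_label == "D" & vg$side %in% c("left", "right"), ]
  )
  volume_anovas <- lapply(names(set_data), function(s) {
    d <- set_data[[s]]
    within <- if (s == "C") "side" else c("region", "side")
    stage(paste0("anova-set-", s),
          mixed_anova(d, dv = "volume_mm3", subject = "subject_id",
                      between = c("vviq_group", "sex"), within = within))
  })
  names(volume_anovas) <- names(set_data)

  # --- per-region t-tests and composite tests -----------------------------
  wide <- .volumes_wide(volumes)
  high_ids <- subjects$subject_id[subjects$vviq_group == "high"]
  low_ids <- subjects$subject_id[subjects$vviq_group == "low"]
  col_set <- volumes$set_label[match(colnames(wide),
                                     paste(volumes$region, volumes$side,
                                           sep = "|"))]
  region_tests <- do.call(rbind, lapply(seq_len(ncol(wide)), function(j) {
    tt <- t_from_summary(as_summary_stats(wide[high_ids, j]),
                         as_summary_stats(wide[low_ids, j]),
                         variance = "welch", tails = config$tails)
    data.frame(column = colnames(wide)[j], set_label = col_set[j],
               t = tt$t, df = tt$df, p = tt$p, d = tt$d,
               high_larger = tt$t > 0, tails = config$tails,
               stringsAsFactors = FALSE)
  }))
  active <- region_tests$set_label %in% c("A", "B")
  sig <- region_tests$p < config$alpha
  counts <- rbind(c(sum(sig & active), sum(sig & !active)),
                  c(sum(!sig & active), sum(!sig & !active)))
  dimnames(counts) <- list(c("significant", "non_significant"),
                           c("active_AB", "control_CD"))
  chi2_active_control <- list(
    counts = counts,
    uncorrected = chi2_2x2(counts, yates = FALSE),
    yates = chi2_2x2(counts, yates = TRUE)
  )
  sign_test <- list(n_regions = sum(active),
                    k_high_larger = sum(region_tests$high_larger[active]),
                    p = sign_consistency(sum(active),
                                         sum(region_tests$high_larger[active])))

  # --- ordering test over the five categories -----------------------------
  aphant_id <- subjects$subject_id[subjects$role == "aphant"][1]
  hphant_id <- subjects$subject_id[subjects$role == "hphant"][1]
  if (is.na(aphant_id))
    aphant_id <- subjects$subject_id[which.min(subjects$vviq_total)]
  if (is.na(hphant_id))
    hphant_id <- subjects$subject_id[which.max(subjects$vviq_total)]
  ordering_input <- data.frame(
    region = colnames(wide),
    hphant = wide[hphant_id, ],
    high_group_mean = colMeans(wide[high_ids, , drop = FALSE]),
    sample_mean = colMeans(wide),
    low_group_mean = colMeans(wide[low_ids, , drop = FALSE]),
    aphant = wide[aphant_id, ],
    stringsAsFactors = FALSE)
  ordering <- ordering_match_count(ordering_input)

  # --- single-case analyses ----------------------------------------------
  meas_cols <- c("avg_error_px", "guess_rate", "misbind_rate", "rt_s",
                 "ident_acc")
  sc_rows <- list()
  case_ids <- c(aphant = aphant_id, hphant = hphant_id)
  for (role in names(case_ids)) {
    case <- case_ids[[role]]
    for (mc in meas_cols) {
      for (cond in unique(summaries$condition)) {
        v <- summaries[summaries$condition == cond, c("subject_id", mc)]
        v <- v[!is.na(v[[mc]]), ]
        x_case <- v[[mc]][v$subject_id == case]
        ctrl <- v[[mc]][v$subject_id != case]
        if (!length(x_case) || length(ctrl) < 2 || stats::sd(ctrl) == 0)
          next
        bay <- single_case_test(x_case, ctrl,
                                n_iter = config$single_case_iters,
                                seed = config$seeds$single_case +
                                  length(sc_rows))
        ch <- crawford_howell_t(x_case, ctrl)
        sc_rows[[length(sc_rows) + 1L]] <- data.frame(
          role = role, measure = mc, condition = cond, case_value = x_case,
          control_mean = mean(ctrl), control_sd = stats::sd(ctrl),
          n_controls = length(ctrl), z_cc = bay$z_cc_point,
          z_cc_lo = bay$z_cc_ci95[1], z_cc_hi = bay$z_cc_ci95[2],
          p_below = bay$p_below, p_two_sided = bay$p_two_sided,
          p_crawford_howell = ch$p, stringsAsFactors = FALSE)
      }
    }
  }
  single_case <- do.call(rbind, sc_rows)

  # aphant vs hphant paired contrast over the active-set volume columns
  act_cols <- which(col_set %in% c("A", "B"))
  pt <- stats::t.test(wide[aphant_id, act_cols], wide[hphant_id, act_cols],
                      paired = TRUE)
  aphant_hphant_paired <- list(t = unname(pt$statistic),
                               df = unname(pt$parameter),
                               p = pt$p.value,
                               ci95 = as.numeric(pt$conf.int),
                               n_regions = length(act_cols))

  structure(list(
    subjects = subjects, group_assignment = ga_vviq, age_assignment = ga_age,
    vstm_summaries = summaries, vstm_group_summary = vstm_group_summary,
    vstm_anovas = vstm_anovas, fisher_combined = fisher_combined,
    volume_anovas = volume_anovas, region_tests = region_tests,
    single_case = single_case, aphant_hphant_paired = aphant_hphant_paired,
    chi2_active_control = chi2_active_control,
    sign_consistency = sign_test, ordering = ordering,
    manifest = list(seed = config$seed, seeds = config$seeds,
                    k = config$k, n_resamples = config$n_resamples,
                    tails = config$tails, alpha = config$alpha,
                    percent_denominator = config$percent_denominator,
                    package_version =
                      as.character(utils::packageVersion("vividmem")))
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Full analysis report\n")
  cat(sprintf("  subjects: %d (high %d / low %d, gap %d VVIQ points)\n",
              nrow(x$subjects), x$group_assignment$n_high,
              x$group_assignment$n_low, x$group_assignment$gap))
  gp <- vapply(x$vstm_anovas[c("error_group", "guess_group",
                               "misbind_group")],
               function(a) a$p[a$effect == "vviq_group"], numeric(1))
  cat(sprintf("  VSTM group p (error/guess/misbind): %.4f / %.4f / %.4f\n",
              gp[1], gp[2], gp[3]))
  cat(sprintf("  Fisher combined p: %.3g\n", x$fisher_combined$p_combined))
  cat(sprintf("  active-vs-control chi2(1) = %.3f (Yates p = %.4g)\n",
              x$chi2_active_control$uncorrected$chi2,
              x$chi2_active_control$yates$p))
  cat(sprintf("  sign consistency: %d/%d high > low, p = %.3g\n",
              x$sign_consistency$k_high_larger,
              x$sign_consistency$n_regions, x$sign_consistency$p))
  cat(sprintf("  ordering: %d/%d regions matched, p = %.3g\n",
              x$ordering$k_matches, x$ordering$n_regions,
              x$ordering$p_at_least_k))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the report tables as CSVs and the run manifest as JSON.
#'
#' @param bundle A `report_bundle` from [run_full_analysis()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$vstm_summaries,
                   file.path(dir, "vstm_summaries.csv"), row.names = FALSE)
  utils::write.csv(bundle$vstm_group_summary,
                   file.path(dir, "vstm_group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$region_tests, file.path(dir, "region_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$single_case, file.path(dir, "single_case.csv"),
                   row.names = FALSE)
  for (s in names(bundle$volume_anovas))
    write_anova_table(bundle$volume_anovas[[s]],
                      file.path(dir, paste0("anova_volumes_set", s, ".csv")))
  for (s in names(bundle$vstm_anovas))
    write_anova_table(bundle$vstm_anovas[[s]],
                      file.path(dir, paste0("anova_vstm_", s, ".csv")))
  composite <- list(
    fisher = bundle$fisher_combined,
    chi2_active_control = list(
      counts = bundle$chi2_active_control$counts,
      chi2 = bundle$chi2_active_control$uncorrected$chi2,
      p = bundle$chi2_active_control$uncorrected$p,
      yates_p = bundle$chi2_active_control$yates$p),
    sign_consistency = bundle$sign_consistency,
    ordering = bundle$ordering[c("n_regions", "k_matches", "per_trial_p",
                                 "p_at_least_k")],
    aphant_hphant_paired = bundle$aphant_hphant_paired)
  jsonlite::write_json(composite, file.path(dir, "composite_tests.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
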