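# Shared fixture builders (all generated in code; no stored data).

# a trial table row with explicit geometry; defaults give a 3-item trial
make_trial <- function(subject_id = "S001", n_items = 3,
                       target = c(700, 900),
                       nt1 = c(200, 300), nt2 = c(1200, 1600),
                       response = target, correct = TRUE,
                       condition = condition_key(n_items, 1),
                       block = 1, trial = 1, rt = 1.5) {
  data.frame(subject_id = subject_id, block = block, trial = trial,
             n_items = n_items, delay_s = 1, condition = condition,
             target_x = target[1], target_y = target[2],
             nt1_x = if (n_items == 3) nt1[1] else NA_real_,
             nt1_y = if (n_items == 3) nt1[2] else NA_real_,
             nt2_x = if (n_items == 3) nt2[1] else NA_real_,
             nt2_y = if (n_items == 3) nt2[2] else NA_real_,
             identified_correctly = correct,
             response_x = response[1], response_y = response[2],
             response_time_s = rt, stringsAsFactors = FALSE)
}

# subject table with fully specified scores (no randomness)
make_subjects <- function(scores, ages = NULL, sexes = NULL) {
  n <- length(scores)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             group = "sample",
             age_years = if (is.null(ages)) rep(60, n) else ages,
             sex = if (is.null(sexes)) rep(c("female", "male"),
                                           length.out = n) else sexes,
             vviq_total = scores,
             scaling_factor = rep(1.2, n),
             role = "none", stringsAsFactors = FALSE)
}

# balanced split-plot long table: g groups x s subjects-per-group x c cells
make_split_plot <- function(y, n_per_group = 2, n_cond = 2) {
  n_subj <- 2 * n_per_group
  d <- expand.grid(subject = sprintf("s%02d", seq_len(n_subj)),
                   cond = paste0("c", seq_len(n_cond)))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n_per_group,
                    "g1", "g2")
  d$y <- y
  d
}
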