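# Summary t-tests, correlation, and the split-plot Type III ANOVA engine.

test_that("the pooled t from printed group summaries matches the published value", {
  tt <- t_from_summary(summary_stats(41.9, 11.99, 10),
                       summary_stats(75.5, 2.72, 10),
                       variance = "pooled", tails = 2)
  expect_equal(tt$df, 18)
  expect_equal(tt$t, -8.6454, tolerance = 0.005)  # printed means/SDs rounded
  expect_lt(tt$p, 1e-5)
  expect_lt(tt$d, 0)  # sign follows mean(a) - mean(b)
})

test_that("identical summaries give t = 0, p = 1", {
  a <- summary_stats(5, 2, 12)
  tt <- t_from_summary(a, a)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
})

test_that("Welch df collapses to the pooled df for equal sds and ns", {
  tw <- t_from_summary(summary_stats(0, 1, 30), summary_stats(0.5, 1, 30),
                       variance = "welch")
  tp <- t_from_summary(summary_stats(0, 1, 30), summary_stats(0.5, 1, 30))
  expect_equal(tw$df, 58)
  expect_equal(tp$df, 58)
  expect_equal(tw$t, tp$t)
})

test_that("degenerate zero-sd inputs are handled as specified", {
  z <- summary_stats(3, 0, 5)
  expect_equal(t_from_summary(z, z)$t, 0)
  expect_error(t_from_summary(z, summary_stats(4, 0, 5)), "infinite")
})

test_that("Pearson correlation handles exact linear and null cases", {
  x <- 1:20
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(123)
  r_null <- pearson_correlation(rnorm(1e4), rnorm(1e4))$r
  expect_lt(abs(r_null), 0.05)
  expect_error(pearson_correlation(x, rep(2, 20)), "variance")
})

test_that("a one-way two-group layout reduces to F = t^2", {
  set.seed(2)
  d <- data.frame(subject = sprintf("s%d", 1:24),
                  g = rep(c("a", "b"), c(14, 10)),  # unbalanced on purpose
                  y = rnorm(24))
  a <- mixed_anova(d, "y", "subject", between = "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
  expect_equal(a$df2, 22)
})

test_that("a textbook 2x2 split-plot matches hand-computed sums of squares", {
  # 4 subjects (2 per group) x 2 conditions
  d <- make_split_plot(y = c(3, 5, 2, 4,    # condition c1: s1..s4
                             7, 9, 4, 8),   # condition c2: s1..s4
                       n_per_group = 2, n_cond = 2)
  a <- mixed_anova(d, "y", "subject", between = "group", within = "cond")
  # hand computation from the classical balanced formulas
  y <- matrix(d$y, nrow = 4)          # subjects x conditions
  gm <- mean(y)
  subj_m <- rowMeans(y)
  grp <- c("g1", "g1", "g2", "g2")
  grp_m <- c(tapply(subj_m, grp, mean))
  cond_m <- colMeans(y)
  cell_m <- rbind(colMeans(y[1:2, ]), colMeans(y[3:4, ]))
  ss_group <- 4 * sum((grp_m - gm)^2)
  ss_subj <- 2 * sum((subj_m - grp_m[grp])^2)
  ss_cond <- 4 * sum((cond_m - gm)^2)
  ss_gxc <- 2 * sum((cell_m - matrix(grp_m, 2, 2) -
                       matrix(cond_m, 2, 2, byrow = TRUE) + gm)^2)
  ss_err <- sum((y - cell_m[ifelse(grp == "g1", 1, 2), ] -
                   subj_m + grp_m[grp])^2)
  expect_equal(a$SS[a$effect == "group"], ss_group, tolerance = 1e-10)
  expect_equal(a$SS[a$effect == "cond"], ss_cond, tolerance = 1e-10)
  expect_equal(a$SS[a$effect == "cond:group"], ss_gxc, tolerance = 1e-10)
  st <- attr(a, "strata")
  expect_equal(st$between$SS_error, ss_subj, tolerance = 1e-10)
  expect_equal(st[["subject:cond"]]$SS_error, ss_err, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "group"],
               (ss_group / 1) / (ss_subj / 2), tolerance = 1e-10)
})

test_that("balanced designs reproduce aov exactly (Type III = Type I)", {
  set.seed(6)
  d <- make_split_plot(y = rnorm(80), n_per_group = 10, n_cond = 4)
  a <- mixed_anova(d, "y", "subject", between = "group", within = "cond")
  ref <- summary(aov(y ~ group * cond + Error(subject / cond), data = d))
  btw <- ref[["Error: subject"]][[1]]
  wthn <- ref[["Error: subject:cond"]][[1]]
  expect_equal(a$SS[a$effect == "group"], btw["group", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "group"], btw["group", "F value"],
               tolerance = 1e-10)
  expect_equal(a$SS[a$effect == "cond"], wthn["cond", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(a$SS[a$effect == "cond:group"], wthn["group:cond", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "cond:group"], wthn["group:cond", "F value"],
               tolerance = 1e-10)
  expect_equal(a$df2[a$effect == "cond"], 54)
})

test_that("Type III SS agree with car::Anova on an unbalanced covariate design", {
  skip_if_not_installed("car")
  set.seed(11)
  subj <- data.frame(subject = sprintf("s%02d", 1:20),
                     grp = rep(c("high", "low"), c(12, 8)),
                     sex = sample(c("f", "m"), 20, TRUE),
                     cov = rnorm(20))
  d <- merge(expand.grid(subject = subj$subject,
                         region = paste0("r", 1:3), side = c("L", "R", "B")),
             subj)
  d$y <- rnorm(nrow(d)) + as.integer(factor(d$region)) +
    (d$side == "B") * 2 + (d$grp == "high") * 0.4
  a <- mixed_anova(d, "y", "subject", between = c("grp", "sex"),
                   within = c("region", "side"), covariate = "cov")
  sm <- aggregate(y ~ subject + grp + sex + cov, d, mean)
  sm$cov <- sm$cov - mean(sm$cov)
  m <- lm(y ~ grp * sex + cov, sm,
          contrasts = list(grp = "contr.sum", sex = "contr.sum"))
  ca <- car::Anova(m, type = 3)
  m_cells <- 9  # subject means average over 9 within cells
  for (eff in c("grp", "sex", "grp:sex", "cov")) {
    expect_equal(a$SS[a$effect == eff & a$stratum == "between"],
                 ca[eff, "Sum Sq"] * m_cells, tolerance = 1e-8)
  }
  expect_equal(unique(a$df2[a$stratum == "between"]), 15)
})

test_that("partial eta squared uses the effect's own error stratum", {
  set.seed(13)
  d <- make_split_plot(y = rnorm(40), n_per_group = 5, n_cond = 4)
  a <- mixed_anova(d, "y", "subject", between = "group", within = "cond")
  st <- attr(a, "strata")
  for (i in seq_len(nrow(a))) {
    expect_equal(a$pes[i],
                 a$SS[i] / (a$SS[i] + st[[a$stratum[i]]]$SS_error))
  }
  expect_true(all(a$pes >= 0 & a$pes <= 1))
  expect_true(all(a$F >= 0))
})

test_that("within-stratum SS decompose additively in balanced designs", {
  set.seed(17)
  d <- make_split_plot(y = rnorm(48), n_per_group = 6, n_cond = 4)
  a <- mixed_anova(d, "y", "subject", between = "group", within = "cond")
  st <- attr(a, "strata")
  # total within-stratum SS via direct orthonormal projection
  y <- matrix(d$y[order(d$cond, d$subject)], nrow = 12)
  M <- contr.poly(4)
  z <- y %*% M
  total_within <- sum(z^2)
  parts <- sum(a$SS[a$stratum == "subject:cond"]) +
    st[["subject:cond"]]$SS_error
  expect_equal(parts, total_within, tolerance = 1e-8)
})

test_that("incomplete within layouts and varying between factors are rejected", {
  d <- make_split_plot(y = rnorm(8))
  expect_error(mixed_anova(d[-1, ], "y", "subject",
                           between = "group", within = "cond"),
               "incomplete|duplicated")
  d2 <- d
  d2$group[1] <- "g2"
  expect_error(mixed_anova(d2, "y", "subject",
                           between = "group", within = "cond"),
               "varies within subject")
  d3 <- d
  d3$y[3] <- NA
  expect_error(mixed_anova(d3, "y", "subject",
                           between = "group", within = "cond"), "missing")
})

test_that("Greenhouse-Geisser correction reports a valid epsilon and keeps df printed uncorrected", {
  set.seed(23)
  d <- make_split_plot(y = rnorm(60), n_per_group = 5, n_cond = 6)
  a0 <- mixed_anova(d, "y", "subject", between = "group", within = "cond")
  ag <- mixed_anova(d, "y", "subject", between = "group", within = "cond",
                    sphericity = "greenhouse-geisser")
  eps <- ag$gg_epsilon[ag$effect == "cond"]
  expect_true(eps > 1 / 5 - 1e-9 && eps <= 1 + 1e-9)
  expect_equal(ag$df1, a0$df1)  # printed df remain uncorrected
  expect_equal(ag$SS, a0$SS)
  expect_true(all(is.na(a0$gg_epsilon)))
})
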