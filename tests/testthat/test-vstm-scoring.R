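# Scoring: localisation error, resampling classifier, condition summaries.

test_that("localisation error is Euclidean distance in pixels", {
  expect_equal(localisation_error(5, 5, 5, 5), 0)
  expect_equal(localisation_error(3, 4, 0, 0), 5)
  expect_error(localisation_error(NA, 1, 0, 0), "missing")
})

test_that("localisation error is invariant under global translation", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(4, 0, 2000)
    shift <- runif(2, -500, 500)
    expect_equal(localisation_error(p[1], p[2], p[3], p[4]),
                 localisation_error(p[1] + shift[1], p[2] + shift[2],
                                    p[3] + shift[1], p[4] + shift[2]))
  }
})

test_that("a response at the target with everything else far away is pure target", {
  cl <- classify_response(response = c(100, 100), target = c(100, 100),
                          nontargets = rbind(c(700, 100), c(100, 700)),
                          pool = rbind(c(900, 900), c(1400, 200)),
                          n_resamples = "exact")
  expect_equal(cl$p_target, 1)
  expect_equal(cl$p_misbind, 0)
  expect_equal(cl$p_guess, 0)
})

test_that("exact mode reproduces the hand-enumerated pool example", {
  # d_target = 10, d_closest_nontarget = 5, pool distances {2, 3, 20, 30}:
  # pool points at 2 and 3 beat both (guessing, 2/4); at 20 and 30 the own
  # non-target at 5 wins (misbinding, 2/4); the target never wins.
  cl <- classify_response(response = c(0, 0), target = c(10, 0),
                          nontargets = rbind(c(0, 5), c(500, 500)),
                          pool = rbind(c(2, 0), c(0, 3), c(-20, 0), c(0, -30)),
                          n_resamples = "exact")
  expect_equal(cl$p_target, 0)
  expect_equal(cl$p_misbind, 0.5)
  expect_equal(cl$p_guess, 0.5)
  expect_identical(cl$n_resamples_used, "exact")
})

test_that("probabilities sum to one and 1-item trials never misbind", {
  set.seed(31)
  for (i in 1:25) {
    pool <- matrix(runif(20, 0, 1500), ncol = 2)
    cl3 <- classify_response(runif(2, 0, 1500), runif(2, 0, 1500),
                             matrix(runif(4, 0, 1500), ncol = 2), pool,
                             n_resamples = 200, seed = i)
    expect_equal(cl3$p_target + cl3$p_misbind + cl3$p_guess, 1,
                 tolerance = 1e-12)
    cl1 <- classify_response(runif(2, 0, 1500), runif(2, 0, 1500), NULL,
                             pool, n_resamples = "exact")
    expect_equal(cl1$p_misbind, 0)
    expect_equal(cl1$p_target + cl1$p_guess, 1, tolerance = 1e-12)
  }
})

test_that("an empty pool is rejected as undefined", {
  expect_error(classify_response(c(0, 0), c(1, 1), NULL,
                                 matrix(numeric(0), ncol = 2)),
               "empty pool")
})

test_that("sampling mode is an unbiased estimate of exact mode", {
  # mean over 200 seeded runs at 5000 resamples deviates from the exact
  # enumeration by well under 0.005 per class
  set.seed(77)
  response <- c(400, 400); target <- c(430, 400)
  nts <- rbind(c(480, 430), c(900, 1200))
  pool <- matrix(runif(60, 0, 1500), ncol = 2)
  ex <- classify_response(response, target, nts, pool, "exact")
  draws <- vapply(1:200, function(s) {
    cl <- classify_response(response, target, nts, pool, 5000, seed = s)
    c(cl$p_target, cl$p_misbind, cl$p_guess)
  }, numeric(3))
  expect_lt(max(abs(rowMeans(draws) -
                      c(ex$p_target, ex$p_misbind, ex$p_guess))), 0.005)
})

test_that("decreasing the distance to target never decreases p_target", {
  set.seed(5)
  pool <- matrix(runif(40, 0, 1500), ncol = 2)
  nts <- rbind(c(600, 900), c(1100, 300))
  response <- c(500, 500)
  d_seq <- seq(900, 0, by = -50)
  p_t <- vapply(d_seq, function(d) {
    classify_response(response, response + c(d, 0), nts, pool,
                      "exact")$p_target
  }, numeric(1))
  expect_true(all(diff(p_t) >= 0))
})

test_that("classify_trials pools non-targets within subject, excluding the own trial", {
  # subject with two 3-item trials; classification of trial 1 may only use
  # trial 2's non-targets as the pool (2 points), and vice versa
  t1 <- make_trial(trial = 1, target = c(100, 100), response = c(100, 100),
                   nt1 = c(800, 800), nt2 = c(1200, 1500))
  t2 <- make_trial(trial = 2, target = c(1400, 1800),
                   response = c(102, 100),  # 2 px from trial 1's target
                   nt1 = c(104, 100), nt2 = c(60, 1900))
  trials <- rbind(t1, t2)
  cl <- classify_trials(trials, n_resamples = "exact")
  # trial 2's response: own nt at 2px... no, own nts are (104,100) d=2 and
  # far; target at d ~ 2166; pool = trial 1's nts, both far -> misbinding
  expect_equal(cl$p_misbind[2], 1)
  # trial 1: response on own target, pool far -> target
  expect_equal(cl$p_target[1], 1)
})

test_that("incorrectly identified trials are excluded from classification but feed the pool", {
  t1 <- make_trial(trial = 1, correct = FALSE)
  t2 <- make_trial(trial = 2, target = c(900, 1000), response = c(900, 1000),
                   nt1 = c(300, 1700), nt2 = c(1300, 400))
  cl <- classify_trials(rbind(t1, t2), n_resamples = "exact")
  expect_true(is.na(cl$p_target[1]))
  expect_false(is.na(cl$p_target[2]))
})

test_that("a subject with no 3-item trials has no pool and is rejected", {
  tr <- make_trial(n_items = 1)
  expect_error(classify_trials(tr, n_resamples = "exact"), "pool")
})

test_that("condition summaries count, average and exclude as specified", {
  trials <- do.call(rbind, lapply(1:30, function(i)
    make_trial(trial = i, correct = i <= 24,
               target = c(500, 500), response = c(530, 540))))
  trials2 <- do.call(rbind, lapply(1:30, function(i)
    make_trial(trial = 30 + i, n_items = 1, condition = "1item_1s",
               target = c(200, 200), response = c(200, 250))))
  s <- summarise_conditions(rbind(trials, trials2))
  r3 <- s[s$condition == "3item_1s", ]
  expect_equal(r3$ident_acc, 0.8)
  expect_equal(r3$n_trials_included, 24)
  expect_equal(r3$avg_error_px, 50)  # constant 30-40-50 offset
  r1 <- s[s$condition == "1item_1s", ]
  expect_equal(r1$avg_error_px, 50)
  # misbinding summaries only for 3-item conditions
  expect_true(is.na(r1$misbind_rate))
})

test_that("misbinding summaries exist for exactly the two 3-item conditions", {
  s <- generate_subjects(2, list(g = list(size = 2, vviq_mean = 60,
                                          vviq_sd = 5, female_ratio = 0.5,
                                          age_mean = 60, age_sd = 5)),
                         plant_extremes = FALSE, seed = 3)
  tr <- generate_cohort_trials(s, seed = 3)
  cl <- classify_trials(tr, n_resamples = "exact")
  sm <- summarise_conditions(tr, cl)
  with_misb <- unique(sm$condition[!is.na(sm$misbind_rate)])
  expect_setequal(with_misb, c("3item_1s", "3item_4s"))
})

test_that("a condition with zero identified-correct trials is flagged, not zero-filled", {
  trials <- do.call(rbind, lapply(1:5, function(i)
    make_trial(trial = i, correct = FALSE)))
  s <- summarise_conditions(trials)
  expect_true(s$all_excluded)
  expect_true(is.na(s$avg_error_px))
  expect_equal(s$ident_acc, 0)
  expect_equal(s$n_trials_included, 0)
})

test_that("misaligned classifications are rejected", {
  trials <- rbind(make_trial(trial = 1), make_trial(trial = 2))
  cl <- classify_trials(trials, n_resamples = "exact")
  expect_error(summarise_conditions(trials, cl[1, ]), "aligned")
})
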