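# The synthetic-data generator: random effects, dropout, category draws,
# the study-shaped preset and the recovery harness.

test_that("random-effect draws honour degenerate and correlated Sigma", {
  Z <- draw_random_effects(10, matrix(0, 2, 2), seed = 1)
  expect_equal(Z, matrix(0, 10, 2))

  S1 <- matrix(c(1, 1, 1, 1), 2)  # correlation 1, equal SDs
  Z1 <- draw_random_effects(50, S1, seed = 2)
  expect_equal(Z1[, 1], Z1[, 2], tolerance = 1e-10)

  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  Z2 <- draw_random_effects(20000, S, seed = 3)
  r <- cor(Z2)[1, 2]
  se <- (1 - 0.8^2) / sqrt(20000)
  expect_lt(abs(r - 0.8), 3 * se)

  expect_error(draw_random_effects(5, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
  expect_identical(draw_random_effects(5, S, seed = 9),
                   draw_random_effects(5, S, seed = 9))
})

test_that("simulation is deterministic, complete under full retention,
           and dropout is monotone", {
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 40, retention = 1)
  d1 <- simulate_mvord(tr, seed = 31)
  d2 <- simulate_mvord(tr, seed = 31)
  expect_identical(d1$data, d2$data)
  expect_true(all(table(d1$data$subject) == length(tr$wave_months)))

  tr2 <- uni_truth(sp, n_subjects = 200, retention = 0.7,
                   waves = seq(0, 84, 12))
  d3 <- simulate_mvord(tr2, seed = 32)
  occ <- split(d3$data$occasion, d3$data$subject)
  # observed occasions are always an uninterrupted prefix of the schedule
  expect_true(all(vapply(occ, function(o) identical(sort(o),
                                                    seq_along(o)), TRUE)))
  expect_lt(mean(lengths(occ)), length(tr2$wave_months))
})

test_that("category frequencies match the analytic pmf without random
           effects", {
  thr <- qlogis(c(0.2, 0.5, 0.9))
  sp <- mvord_spec(outcome_def("y", 4), fixed = character(),
                   random = random_structure(FALSE, FALSE), time = "age")
  tr <- truth_config(sp, thresholds = list(y = thr),
                     beta = list(y = list()), sds = numeric(0),
                     cor = diag(0), n_subjects = 4000,
                     wave_months = seq(0, 48, 12), retention = 1)
  d <- simulate_mvord(tr, seed = 33)
  n <- nrow(d$data)
  freq <- as.numeric(table(factor(d$data$y, levels = 0:3))) / n
  target <- c(0.2, 0.3, 0.4, 0.1)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(freq - target) <= 3 * se))
})

test_that("an NPO truth with crossed cutpoints on the support is refused", {
  sp <- uni_spec(4, "per_cutpoint", terms = "age")
  tr <- truth_config(sp, thresholds = list(y = c(-1, -0.5, 0)),
                     beta = list(y = list(age = c(0.1, -0.4, -0.9))),
                     sds = c(1, 0.3), cor = matrix(c(1, 0, 0, 1), 2),
                     n_subjects = 20, wave_months = seq(0, 48, 12))
  expect_error(simulate_mvord(tr, seed = 34), "invalid truth")
})

test_that("truth validation catches inconsistent inputs", {
  sp <- uni_spec(4, "shared")
  expect_error(uni_truth(sp, retention = 0), "retention")
  expect_error(
    truth_config(sp, thresholds = list(y = c(1, 0.5, 2)),
                 beta = list(y = list(age = -0.2, gender = 0.5)),
                 sds = c(1, 0.3), cor = diag(2)),
    "strictly increasing"
  )
  bad_cor <- matrix(c(1, 2, 2, 1), 2)
  expect_error(
    truth_config(sp, thresholds = list(y = c(-1, 0.5, 2)),
                 beta = list(y = list(age = -0.2, gender = 0.5)),
                 sds = c(1, 0.3), cor = bad_cor),
    "positive semidefinite"
  )
})

test_that("study preset reproduces the cohort shape", {
  pr <- study_preset()
  expect_equal(pr$n_subjects, 1263L)
  expect_equal(pr$wave_months, c(0, 6, 15, 24, 48, 60, 72, 84))
  expect_equal(pr$p_male, 1 - 0.566)
  expect_equal(vapply(pr$spec$outcomes, `[[`, "", "name"),
               c("Cig", "Alc", "Marij"))
  expect_true(all(vapply(pr$spec$outcomes, `[[`, 0L,
                         "n_categories") == 5L))
  d <- simulate_mvord(pr, seed = 35)
  df <- d$data
  expect_equal(length(unique(df$subject)), 1263L)
  mobs <- nrow(df) / 1263
  expect_gte(mobs, 6.5)
  expect_lte(mobs, 7.1)
  # gender split close to the published share of females
  pf <- 1 - mean(tapply(df$gender, df$subject, function(g) g[1]))
  expect_lt(abs(pf - 0.566), 3 * sqrt(0.566 * 0.434 / 1263))
})

test_that("negative intercept-slope correlation emulates a ceiling
           effect in the drawn effects", {
  pr <- study_preset()
  W <- draw_random_effects(4000, pr$Sigma, seed = 36)
  # each outcome: baseline level and age trend negatively correlated
  for (k in 1:3) {
    expect_lt(cor(W[, 2 * k - 1], W[, 2 * k]), 0)
  }
  # inter-outcome association: baselines positively correlated
  expect_gt(cor(W[, 1], W[, 3]), 0)
})

test_that("empirical cumulative logits from a near-degenerate simulation
           track the generating linear predictor", {
  sp <- mvord_spec(outcome_def("y", 4), fixed = c(gender = "shared"),
                   random = random_structure(TRUE, TRUE), time = "age")
  tr <- truth_config(sp, thresholds = list(y = c(-0.8, 0.4, 1.6)),
                     beta = list(y = list(gender = 0.6)),
                     sds = c(1e-4, 1e-5),
                     cor = matrix(c(1, 0, 0, 1), 2),
                     n_subjects = 6000, wave_months = 0, retention = 1)
  d <- simulate_mvord(tr, seed = 37)
  cl <- observed_cumulative_logits(category_proportions(d, by = "gender"))
  for (g in c(0, 1)) {
    obs <- cl$logit[cl$gender == g][order(cl$cutpoint[cl$gender == g])]
    expected <- c(-0.8, 0.4, 1.6) + 0.6 * g
    expect_equal(obs, expected, tolerance = 0.12)
  }
})

test_that("recovery harness is deterministic and reports coherent
           summaries", {
  sp <- uni_spec(3, "shared", terms = "age")
  tr <- truth_config(sp, thresholds = list(y = c(-0.5, 1)),
                     beta = list(y = list(age = -0.2)),
                     sds = c(0.8, 0.2), cor = matrix(c(1, 0, 0, 1), 2),
                     n_subjects = 60, wave_months = seq(0, 36, 12),
                     retention = 1)
  fo <- fast_options(se = TRUE, nodes = 5)
  r1 <- recovery_experiment(tr, 2, fo, seed = 100)
  r2 <- recovery_experiment(tr, 2, fo, seed = 100)
  expect_identical(r1, r2)
  expect_true(all(r1$rmse >= abs(r1$bias) - 1e-12))
  expect_true(all(r1$coverage >= 0 & r1$coverage <= 1))
  expect_equal(attr(r1, "replicates"), 2L)
  expect_setequal(unique(r1$type), c("threshold", "coef", "re_sd"))
})
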