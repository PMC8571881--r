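# Starting values, maximum-likelihood fitting, standard errors and the
# random-effect correlation surface.

test_that("starting values follow the documented recipe", {
  d <- counts_data(c(10, 10, 20, 40, 20))
  sp <- mvord_spec(outcome_def("y", 5), fixed = character(),
                   random = random_structure(TRUE, TRUE), time = "age")
  iv <- initial_values(d, sp)
  cum <- cumsum(c(10, 10, 20, 40, 20) + 0.5)[-5]
  expect_equal(iv$thresholds$y, log(cum / (sum(c(10, 10, 20, 40, 20)) +
                                             2.5 - cum)),
               tolerance = 1e-12)
  # d = 2 start: Sigma_w = 0.25 I
  expect_equal(iv$L %*% t(iv$L), diag(0.25, 2))

  dg <- counts_data(c(40, 0, 0, 0))
  expect_error(initial_values(dg, mvord_spec(outcome_def("y", 4),
                                             random = random_structure(
                                               FALSE, FALSE))),
               "fewer than two observed categories")
})

test_that("intercept-only fit without random effects reproduces the
           empirical cumulative logits", {
  d <- counts_data(c(10, 10, 20, 40, 20))
  sp <- mvord_spec(outcome_def("y", 5), fixed = character(),
                   random = random_structure(FALSE, FALSE), time = "age")
  fit <- mvord_fit(d, sp)
  emp <- log(c(0.1, 0.2, 0.4, 0.8) / (1 - c(0.1, 0.2, 0.4, 0.8)))
  expect_true(fit$converged)
  expect_equal(fit$params$thresholds$y, emp, tolerance = 1e-6)
})

test_that("d = 0 proportional-odds fit agrees with an independent fitter", {
  sp <- uni_spec(4, "shared", random = FALSE)
  tr <- uni_truth(uni_spec(4, "shared"), n_subjects = 150, retention = 1,
                  sds = c(0.5, 0.1))
  d <- simulate_mvord(tr, seed = 15)
  fit <- mvord_fit(d, sp)
  df <- d$data
  df$yf <- factor(df$y, ordered = TRUE)
  pol <- MASS::polr(yf ~ age + gender, data = df, method = "logistic",
                    Hess = TRUE)
  # polr parameterizes logit P(Y <= c) = zeta_c - x beta
  expect_equal(fit$loglik, as.numeric(logLik(pol)), tolerance = 1e-6)
  expect_equal(fit$params$beta$y$age, -unname(coef(pol)["age"]),
               tolerance = 1e-4)
  expect_equal(fit$params$thresholds$y, unname(pol$zeta),
               tolerance = 1e-4)
})

test_that("closed-form binomial standard error is recovered", {
  # binary intercept-only, n0 = n1 = 50: SE = sqrt(1 / (n p (1 - p))) = 0.2
  d <- counts_data(c(50, 50))
  sp <- mvord_spec(outcome_def("y", 2), fixed = character(),
                   random = random_structure(FALSE, FALSE), time = "age")
  fit <- mvord_fit(d, sp)
  expect_equal(fit$coef_table$se, 0.2, tolerance = 1e-6)
})

test_that("refitting from the optimum is stationary", {
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 60)
  d <- simulate_mvord(tr, seed = 16)
  fit <- mvord_fit(d, sp, fast_options())
  refit <- mvord_fit(d, sp, fast_options(), start = fit$theta)
  expect_lte(refit$iterations, 2L)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-8)
  # monotone improvement from the starting point
  expect_gte(fit$loglik, fit$loglik_start)
})

test_that("relabelling outcomes permutes estimates and correlations", {
  trB <- bi_truth(n_subjects = 80, waves = seq(0, 36, 12))
  d <- simulate_mvord(trB, seed = 17)
  spAB <- trB$spec
  outsBA <- rev(spAB$outcomes)
  spBA <- mvord_spec(outsBA, fixed = c(age = "shared", gender = "shared"),
                     random = random_structure(TRUE, TRUE, "full"),
                     time = "age")
  fo <- fast_options(se = TRUE, nodes = 7)
  fAB <- mvord_fit(d, spAB, fo)
  fBA <- mvord_fit(d, spBA, fo)
  # exact in the model; up to quadrature error in practice, because the
  # Cholesky factor (and hence the scaled point set) is order-dependent
  expect_equal(fAB$loglik, fBA$loglik, tolerance = 1e-4)
  expect_equal(fAB$params$thresholds$y1, fBA$params$thresholds$y1,
               tolerance = 1e-2)
  cAB <- re_correlation(fAB)
  cBA <- re_correlation(fBA)
  attr(cAB, "se") <- NULL
  attr(cBA, "se") <- NULL
  perm <- c("y2Int", "y2Age", "y1Int", "y1Age")
  expect_equal(unname(cBA), unname(cAB[perm, perm]), tolerance = 2e-2)
})

test_that("fitted correlation surface is labelled in study order", {
  trB <- bi_truth(n_subjects = 60, waves = seq(0, 36, 12))
  d <- simulate_mvord(trB, seed = 18)
  fit <- mvord_fit(d, trB$spec, fast_options(se = TRUE, nodes = 5))
  rc <- re_correlation(fit)
  expect_equal(rownames(rc), c("y1Int", "y1Age", "y2Int", "y2Age"))
  expect_equal(diag(rc), c(y1Int = 1, y1Age = 1, y2Int = 1, y2Age = 1))
  expect_equal(rc, t(rc))
  ev <- eigen(rc, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-8)
  # preset labels reproduce the published ordering convention
  expect_equal(mvordmix:::re_labels(study_preset()$spec),
               c("CigInt", "CigAge", "AlcInt", "AlcAge",
                 "MarijInt", "MarijAge"))
  # d < 2 has no correlation surface
  sp1 <- mvord_spec(outcome_def("y", 3), fixed = character(),
                    random = random_structure(TRUE, FALSE), time = "age")
  tr1 <- truth_config(sp1, thresholds = list(y = c(-0.5, 1)),
                      beta = list(y = list()), sds = 1,
                      cor = matrix(1, 1, 1), n_subjects = 30)
  f1 <- mvord_fit(simulate_mvord(tr1, seed = 19), sp1, fast_options())
  expect_error(re_correlation(f1), "d >= 2")
})

test_that("covariance of estimates matches the curvature of a quadratic
           surrogate", {
  # self-test of the information machinery: for the d = 0 binomial fit the
  # observed information equals n p (1 - p) analytically (checked above);
  # here check vcov is symmetric PSD and SEs positive on a mixed fit
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 80)
  d <- simulate_mvord(tr, seed = 20)
  fit <- mvord_fit(d, sp, fast_options(se = TRUE))
  expect_true(fit$se_defined)
  expect_true(all(fit$coef_table$se > 0))
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  expect_true(all(fit$coef_table$p >= 0 & fit$coef_table$p <= 1))
})

test_that("fitting under the adaptive rule reaches the same optimum as
           the fixed-point rule", {
  sp <- uni_spec(3, "shared", terms = "age")
  tr <- truth_config(sp, thresholds = list(y = c(-0.5, 1)),
                     beta = list(y = list(age = -0.2)),
                     sds = c(0.8, 0.2), cor = matrix(c(1, 0, 0, 1), 2),
                     n_subjects = 50, wave_months = seq(0, 24, 12),
                     retention = 1)
  d <- simulate_mvord(tr, seed = 28)
  f_gh <- mvord_fit(d, sp, fast_options(nodes = 15))
  f_agh <- mvord_fit(d, sp,
                     fit_options(integration = integration_rule("agh",
                                                                nodes = 9),
                                 se = FALSE, grad_tol = 5e-3))
  expect_equal(f_agh$loglik, f_gh$loglik, tolerance = 1e-5)
  # compare on the natural scale: collapsed variances sit on a flat ridge
  # of the log-Cholesky scale
  expect_equal(f_agh$params$thresholds$y, f_gh$params$thresholds$y,
               tolerance = 0.01)
  expect_equal(f_agh$params$beta$y$age, f_gh$params$beta$y$age,
               tolerance = 0.01)
  expect_lt(max(abs(f_agh$re_sds - f_gh$re_sds)), 0.02)
})

test_that("standard errors shrink like one over root n", {
  sp <- uni_spec(4, "shared")
  se_at <- function(n, seed) {
    tr <- uni_truth(sp, n_subjects = n, retention = 1)
    fit <- mvord_fit(simulate_mvord(tr, seed = seed), sp,
                     fast_options(se = TRUE))
    fit$coef_table$se[fit$coef_table$term == "age"]
  }
  r <- se_at(200, 21) / se_at(800, 22)
  expect_gt(r, 1.5)
  expect_lt(r, 2.7)
})
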