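# Conditional probabilities, marginal likelihood and its gradient.

test_that("logistic link and category pmf behave as defined", {
  expect_equal(cumulative_probability(0), 0.5)
  expect_equal(cumulative_probability(log(3)), 0.75)
  p <- cumulative_probability(-50)
  expect_true(p > 0 && p < 1e-20)
  expect_true(all(diff(cumulative_probability(seq(-700, 700, by = 50))) >=
                    0))

  expect_equal(as.numeric(category_pmf(c(0.2, 0.5, 0.9))),
               c(0.2, 0.3, 0.4, 0.1))
  expect_equal(as.numeric(category_pmf(0.5)), c(0.5, 0.5))
  crossed <- category_pmf(c(0.5, 0.4))
  expect_equal(attr(crossed, "violations"), 1L)
  expect_equal(as.numeric(crossed)[2], 1e-10)
  expect_error(category_pmf(c(0.2, 1.2)), "inside")
  set.seed(4)
  for (i in 1:10) {
    cum <- sort(runif(4, 0.01, 0.99))
    expect_equal(sum(category_pmf(cum)), 1, tolerance = 1e-12)
  }
})

test_that("conditional subject loglik is the sum over observed cells", {
  sp <- uni_spec(4, "shared")
  df <- data.frame(subject = 1, occasion = 1:2, age = c(0, 1),
                   gender = 1, y = c(0L, 2L))
  d <- long_ordinal_data(df, sp$outcomes)
  params <- list(thresholds = list(y = c(-1, 0.5, 2)),
                 beta = list(y = list(age = -0.2, gender = 0.5)),
                 L = diag(0.7, 2))
  theta <- pack_parameters(sp, params)
  w <- c(0.3, -0.1)
  # brute-force oracle: per-occasion pmf via the cumulative link
  eta <- function(thr_c, t) thr_c - 0.2 * t + 0.5 + w[1] + w[2] * t
  p1 <- plogis(eta(-1, 0))                       # y = 0 at t = 0
  cum2 <- plogis(c(eta(-1, 1), eta(0.5, 1), eta(2, 1)))
  p2 <- cum2[3] - cum2[2]                        # y = 2 at t = 1
  expect_equal(conditional_loglik_subject(d, sp, theta, 1, w),
               log(p1) + log(p2), tolerance = 1e-12)

  # all cells missing contribute nothing
  df2 <- df
  df2$subject <- 2
  d2 <- long_ordinal_data(rbind(df, df2), sp$outcomes)
  d2$data$y[d2$data$subject == 2] <- NA_integer_
  expect_equal(conditional_loglik_subject(d2, sp, theta, 2, w), 0)
})

test_that("binary symmetric random intercept integrates to one half", {
  sp <- mvord_spec(outcome_def("y", 2), fixed = character(),
                   random = random_structure(TRUE, FALSE), time = "age")
  df <- data.frame(subject = 1, occasion = 1, age = 0, y = 0L)
  d <- long_ordinal_data(df, sp$outcomes)
  theta <- pack_parameters(sp, list(thresholds = list(y = 0),
                                    beta = list(y = list()),
                                    L = matrix(1, 1, 1)))
  # P(Y = 0) = E[expit(nu)] = 0.5 by symmetry
  ll <- marginal_loglik(d, sp, theta, integration_rule("agh", nodes = 21))
  expect_equal(as.numeric(ll), log(0.5), tolerance = 1e-8)
})

test_that("marginal loglik matches an independent 1-d integral", {
  sp <- mvord_spec(outcome_def("y", 2), fixed = character(),
                   random = random_structure(TRUE, FALSE), time = "age")
  df <- data.frame(subject = 1, occasion = 1, age = 0, y = 0L)
  d <- long_ordinal_data(df, sp$outcomes)
  theta <- pack_parameters(sp, list(thresholds = list(y = 0.5),
                                    beta = list(y = list()),
                                    L = matrix(1, 1, 1)))
  oracle <- integrate(function(v) plogis(0.5 + v) * dnorm(v), -10, 10,
                      rel.tol = 1e-12)$value
  for (m in list(integration_rule("agh", nodes = 21),
                 integration_rule("gh", nodes = 41),
                 integration_rule("grid", nodes = 3001))) {
    expect_equal(as.numeric(marginal_loglik(d, sp, theta, m)), log(oracle),
                 tolerance = 1e-8)
  }
})

test_that("tiny random-effect variance recovers the conditional loglik", {
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 20)
  d <- simulate_mvord(tr, seed = 5)
  params <- list(thresholds = tr$thresholds,
                 beta = tr$beta, L = diag(1e-6, 2))
  theta <- pack_parameters(sp, params)
  ll <- marginal_loglik(d, sp, theta, integration_rule("gh", nodes = 7))
  cond <- sum(vapply(unique(d$data$subject), function(s) {
    conditional_loglik_subject(d, sp, theta, s, c(0, 0))
  }, 0.0))
  expect_equal(as.numeric(ll), cond, tolerance = 1e-6)
})

test_that("d = 0 reduces the marginal to the conditional likelihood", {
  sp <- uni_spec(4, "shared", random = FALSE)
  tr <- uni_truth(uni_spec(4, "shared"), n_subjects = 15)
  d <- simulate_mvord(tr, seed = 6)
  theta <- pack_parameters(sp, list(thresholds = tr$thresholds,
                                    beta = tr$beta, L = matrix(0, 0, 0)))
  ll <- marginal_loglik(d, sp, theta)
  cond <- sum(vapply(unique(d$data$subject), function(s) {
    conditional_loglik_subject(d, sp, theta, s, numeric(0))
  }, 0.0))
  expect_equal(as.numeric(ll), cond, tolerance = 1e-10)
  expect_true(ll <= 0)
})

test_that("adaptive quadrature converges to the dense-grid oracle", {
  set.seed(7)
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 8, waves = seq(0, 36, 12))
  d <- simulate_mvord(tr, seed = 8)
  theta <- pack_parameters(sp, list(thresholds = tr$thresholds,
                                    beta = tr$beta,
                                    Sigma = tr$Sigma))
  oracle <- as.numeric(marginal_loglik(d, sp, theta,
                                       integration_rule("grid",
                                                        nodes = 501)))
  errs <- vapply(c(3, 7, 21), function(q) {
    abs(as.numeric(marginal_loglik(d, sp, theta,
                                   integration_rule("agh", nodes = q))) -
          oracle)
  }, 0.0)
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[3], 1e-6)
})

test_that("block-diagonal likelihood is additive over outcomes", {
  outs <- list(outcome_def("a", 4), outcome_def("b", 3))
  spJ <- mvord_spec(outs, fixed = c(age = "shared"),
                    random = random_structure(TRUE, TRUE,
                                              "block_diagonal"),
                    time = "age")
  tr <- truth_config(spJ,
                     thresholds = list(a = c(-1, 0.5, 2), b = c(-0.5, 1.2)),
                     beta = list(a = list(age = -0.2), b = list(age = 0.1)),
                     sds = c(1, 0.3, 0.8, 0.2), cor = diag(4),
                     n_subjects = 40, wave_months = seq(0, 48, 12))
  d <- simulate_mvord(tr, seed = 9)
  theta <- pack_parameters(spJ, list(thresholds = tr$thresholds,
                                     beta = tr$beta, Sigma = tr$Sigma))
  rule <- integration_rule("gh", nodes = 7)
  llJ <- as.numeric(marginal_loglik(d, spJ, theta, rule))
  llU <- 0
  for (k in 1:2) {
    spU <- mvord_spec(outs[[k]], fixed = c(age = "shared"),
                      random = random_structure(TRUE, TRUE), time = "age")
    nm <- outs[[k]]$name
    thU <- pack_parameters(spU, list(
      thresholds = tr$thresholds[nm],
      beta = tr$beta[nm],
      Sigma = tr$Sigma[(2 * k - 1):(2 * k), (2 * k - 1):(2 * k)]
    ))
    llU <- llU + as.numeric(marginal_loglik(d, spU, thU, rule))
  }
  expect_equal(llJ, llU, tolerance = 1e-8)
})

test_that("PO vectors embed in the NPO space with unchanged likelihood", {
  spP <- uni_spec(4, "shared")
  spN <- uni_spec(4, "per_cutpoint")
  tr <- uni_truth(spP, n_subjects = 30)
  d <- simulate_mvord(tr, seed = 10)
  thP <- pack_parameters(spP, list(thresholds = tr$thresholds,
                                   beta = tr$beta, Sigma = tr$Sigma))
  thN <- expand_po_to_npo(thP, spP, spN)
  pN <- unpack_parameters(spN, thN)
  expect_equal(pN$beta$y$age, rep(-0.2, 3))
  rule <- integration_rule("gh", nodes = 7)
  expect_equal(as.numeric(marginal_loglik(d, spN, thN, rule)),
               as.numeric(marginal_loglik(d, spP, thP, rule)),
               tolerance = 1e-12)
  expect_equal(restrict_npo_to_po(thN, spP, spN), thP, tolerance = 1e-12)
  expect_error(expand_po_to_npo(thP, spP, uni_spec(5, "per_cutpoint")),
               "not nested")
})

test_that("analytic gradients equal central finite differences", {
  sp <- uni_spec(4, "per_cutpoint")
  tr <- uni_truth(sp, n_subjects = 25)
  d <- simulate_mvord(tr, seed = 11)
  theta <- pack_parameters(sp, list(thresholds = tr$thresholds,
                                    beta = tr$beta, Sigma = tr$Sigma))
  for (rule in list(integration_rule("gh", nodes = 7),
                    integration_rule("qmc", points = 96, seed = 2))) {
    ga <- loglik_gradient(d, sp, theta, rule, method = "analytic")
    gn <- loglik_gradient(d, sp, theta, rule, method = "numeric")
    expect_equal(ga, gn, tolerance = 1e-6)
  }
})

test_that("gradient respects outcome exchange symmetry", {
  # two outcomes with identical data and parameters: matching gradient
  # coordinates must agree
  outs <- list(outcome_def("a", 4), outcome_def("b", 4))
  sp <- mvord_spec(outs, fixed = c(age = "shared"),
                   random = random_structure(TRUE, TRUE,
                                             "block_diagonal"),
                   time = "age")
  set.seed(12)
  df <- data.frame(subject = rep(1:20, each = 3),
                   occasion = rep(1:3, 20),
                   age = rep(0:2, 20),
                   y = sample(0:3, 60, TRUE))
  df$a <- df$y; df$b <- df$y; df$y <- NULL
  d <- long_ordinal_data(df, outs)
  theta <- pack_parameters(sp, list(
    thresholds = list(a = c(-1, 0, 1), b = c(-1, 0, 1)),
    beta = list(a = list(age = -0.1), b = list(age = -0.1)),
    L = diag(c(0.8, 0.3, 0.8, 0.3))
  ))
  g <- loglik_gradient(d, sp, theta, integration_rule("gh", nodes = 7))
  pidx <- parameter_index(sp)
  ga <- g[pidx$outcome %in% "a"]
  gb <- g[pidx$outcome %in% "b"]
  expect_equal(ga, gb, tolerance = 1e-8)
  # chol blocks: positions (1,1),(2,1),(2,2) vs (3,3),(4,3),(4,4)
  gc <- g[pidx$type == "chol"]
  expect_equal(gc[1:3], gc[4:6], tolerance = 1e-8)
})

test_that("gradient is near zero at a converged optimum", {
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 80)
  d <- simulate_mvord(tr, seed = 13)
  fit <- mvord_fit(d, sp, fast_options())
  g <- loglik_gradient(d, sp, fit$theta, fit$rule)
  expect_lt(max(abs(g)), 1e-3)
})

test_that("a positive fitted coefficient raises every fitted P(Y <= c)", {
  # the link models P(Y <= c): a positive coefficient shifts mass toward
  # lower categories (stochastically smaller outcome)
  sp <- uni_spec(4, "shared")
  tr <- uni_truth(sp, n_subjects = 120)  # gender truth is +0.5
  d <- simulate_mvord(tr, seed = 14)
  fit <- mvord_fit(d, sp, fast_options())
  b_gender <- fit$params$beta$y$gender
  expect_gt(b_gender, 0)
  cv <- predict_cumulative_curves(
    fit, prediction_grid(list(gender = c(0, 1)), times = c(0, 2, 4))
  )
  # probability columns are P(Y >= c+1): positive coefficient lowers them
  p0 <- cv$probability[cv$gender == 0]
  p1 <- cv$probability[cv$gender == 1]
  expect_true(all(p1 < p0))
})
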