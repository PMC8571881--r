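# Shared fixtures: small specifications, truths and fast fit options used
# across the test files. Everything is generated in code at test time.

uni_outcome <- function(name = "y", n_categories = 4L) {
  outcome_def(name, n_categories)
}

# univariate spec with random intercept + slope
uni_spec <- function(n_categories = 4L, prop = "shared",
                     terms = c("age", "gender"), random = TRUE,
                     name = "y") {
  fixed <- stats::setNames(rep(prop, length(terms)), terms)
  mvord_spec(uni_outcome(name, n_categories), fixed = fixed,
             random = if (random) random_structure(TRUE, TRUE) else
               random_structure(FALSE, FALSE),
             time = "age")
}

uni_truth <- function(spec = uni_spec(), n_subjects = 100L,
                      waves = seq(0, 48, by = 12), retention = 0.95,
                      sds = c(1, 0.3), rho = -0.3) {
  d <- spec$d
  cr <- if (d == 2L) matrix(c(1, rho, rho, 1), 2) else diag(d)
  nm <- spec$outcomes[[1]]$name
  beta <- list()
  beta[[nm]] <- list()
  C <- spec$outcomes[[1]]$n_categories - 1L
  for (tm in spec$terms) {
    b0 <- switch(tm, age = -0.2, gender = 0.5, 0.1)
    beta[[nm]][[tm]] <- if (spec$prop[1, tm] == "shared") b0 else
      rep(b0, C)
  }
  thr <- list()
  thr[[nm]] <- seq(-1, by = 1.2, length.out = C)
  truth_config(spec, thresholds = thr, beta = beta,
               sds = if (d > 0) sds[seq_len(d)] else numeric(0), cor = cr,
               n_subjects = n_subjects, wave_months = waves,
               p_male = 0.5, baseline_bins = 0L, retention = retention)
}

# K = 2 truth with cross-outcome random-effect correlation rho_x
bi_truth <- function(n_subjects = 300L, rho_x = 0.5, rho_w = -0.3,
                     n_categories = 4L, waves = seq(0, 60, by = 12),
                     terms = c("age", "gender")) {
  outs <- list(outcome_def("y1", n_categories),
               outcome_def("y2", n_categories))
  fixed <- stats::setNames(rep("shared", length(terms)), terms)
  sp <- mvord_spec(outs, fixed = fixed,
                   random = random_structure(TRUE, TRUE, "full"),
                   time = "age")
  cr <- kronecker(matrix(c(1, rho_x, rho_x, 1), 2),
                  matrix(c(1, rho_w, rho_w, 1), 2))
  C <- n_categories - 1L
  truth_config(
    sp,
    thresholds = list(y1 = seq(-1, by = 1.2, length.out = C),
                      y2 = seq(-0.5, by = 1.2, length.out = C)),
    beta = list(y1 = list(age = -0.2, gender = 0.5),
                y2 = list(age = -0.3, gender = 0.3)),
    sds = c(1, 0.3, 1, 0.3), cor = cr,
    n_subjects = n_subjects, wave_months = waves, p_male = 0.5,
    baseline_bins = 0L, retention = 1
  )
}

gh_rule <- function(nodes = 7L) integration_rule("gh", nodes = nodes)

fast_options <- function(..., se = FALSE, nodes = 7L) {
  fit_options(integration = gh_rule(nodes), se = se, ...)
}

# toy cross-sectional table with given category counts (one outcome, d = 0)
counts_data <- function(counts, name = "y") {
  y <- rep(seq_along(counts) - 1L, times = counts)
  df <- data.frame(subject = seq_along(y), occasion = 1L)
  df[[name]] <- y
  long_ordinal_data(df, list(outcome_def(name, length(counts))))
}
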