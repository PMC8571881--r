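# Estimation: maximum marginal likelihood via quasi-Newton optimization on
# the unconstrained parameter vector, observed-information standard errors,
# and the fitted random-effect covariance/correlation.

#' Fitting options
#'
#' @param loglik_tol Relative log-likelihood change tolerance.
#' @param grad_tol Gradient max-norm tolerance at the reported optimum.
#' @param max_iter Maximum optimizer iterations.
#' @param integration An [integration_rule()], or `NULL` to pick a default
#'   by random-effect dimension (product Gauss-Hermite up to d = 3,
#'   quasi-Monte Carlo beyond).
#' @param seed Seed for the QMC point-set shift (echoed into the fit).
#' @param se Compute standard errors after convergence.
#' @param restarts Optimizer restarts allowed when the gradient tolerance
#'   is not yet met.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(loglik_tol = 1e-8, grad_tol = 1e-4,
                        max_iter = 500L, integration = NULL, seed = 1L,
                        se = TRUE, restarts = 2L) {
  stopifnot(loglik_tol > 0, grad_tol > 0, max_iter >= 1L)
  structure(
    list(loglik_tol = loglik_tol, grad_tol = grad_tol,
         max_iter = as.integer(max_iter), integration = integration,
         seed = as.integer(seed), se = isTRUE(se),
         restarts = as.integer(restarts)),
    class = "fit_options"
  )
}

#' Starting values for a fit
#'
#' Thresholds come from the continuity-corrected empirical cumulative
#' logits of each outcome's pooled category counts; fixed coefficients from
#' a per-outcome proportional-odds fit without random effects (replicated
#' across cutpoints for cutpoint-specific terms); the Cholesky factor
#' starts at 0.5 times the identity (Sigma_w = 0.25 I).
#'
#' @param data An `mvord_data` object.
#' @param spec An [mvord_spec()].
#' @return An `mvord_params` list (see [unpack_parameters()]).
#' @export
initial_values <- function(data, spec) {
  df <- data$data
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  thresholds <- list()
  for (k in seq_len(spec$K)) {
    od <- spec$outcomes[[k]]
    y <- df[[od$name]]
    counts <- tabulate(y + 1L, nbins = od$n_categories)
    if (sum(counts > 0) < 2L) {
      stop("outcome '", od$name,
           "' has fewer than two observed categories", call. = FALSE)
    }
    cc <- counts + 0.5
    p <- cumsum(cc)[-od$n_categories] / sum(cc)
    thresholds[[od$name]] <- log(p / (1 - p))
  }
  beta <- list()
  simple <- length(spec$terms) == 0L
  for (k in seq_len(spec$K)) {
    nm <- onames[k]
    C <- spec$outcomes[[k]]$n_categories - 1L
    bk <- list()
    if (!simple) {
      # shared-coefficient, no-random-effects fit of this outcome alone
      uspec <- mvord_spec(
        outcomes = list(spec$outcomes[[k]]),
        fixed = stats::setNames(rep("shared", length(spec$terms)),
                                spec$terms),
        random = random_structure(FALSE, FALSE),
        time = spec$time
      )
      u0 <- list(thresholds = thresholds[nm],
                 beta = stats::setNames(
                   list(stats::setNames(
                     as.list(rep(0, length(spec$terms))), spec$terms)),
                   nm),
                 L = matrix(0, 0, 0))
      ufit <- mvord_fit(data, uspec,
                        fit_options(se = FALSE, restarts = 1L),
                        start = pack_parameters(uspec, u0))
      ub <- ufit$params$beta[[nm]]
      for (tm in spec$terms) {
        bk[[tm]] <- if (spec$prop[k, tm] == "shared") ub[[tm]] else
          rep(ub[[tm]], C)
      }
    }
    beta[[nm]] <- bk
  }
  L <- diag(0.5, spec$d)
  structure(list(thresholds = thresholds, beta = beta, L = L),
            class = "mvord_params")
}

#' Fit a multivariate mixed cumulative logit model
#'
#' Maximizes the marginal log-likelihood over the unconstrained parameter
#' vector with a quasi-Newton method (PORT routines via [stats::nlminb()])
#' using the analytic gradient of the integration rule's approximation.
#' The standardized point set is frozen for the whole fit, so the objective
#' is deterministic and smooth; the fit is reproducible given
#' `options$seed`. Non-convergence is reported in the returned object,
#' never silently.
#'
#' @param data An `mvord_data` object.
#' @param spec An [mvord_spec()].
#' @param options A [fit_options()] object.
#' @param start Optional packed starting vector (default
#'   [initial_values()]).
#' @return An object of class `mvord_fit`: structured estimates
#'   (`$params`), packed vector (`$theta`), `$loglik`, `$converged`,
#'   `$iterations`, Sigma_w and its correlation matrix, crossed-cutpoint
#'   violation report, the integration settings echo, and (if requested)
#'   the observed-information covariance of the estimates with coefficient
#'   and correlation tables.
#' @export
mvord_fit <- function(data, spec, options = fit_options(), start = NULL) {
  stopifnot(inherits(options, "fit_options"))
  frame <- build_frame(data, spec)
  rule <- options$integration %||% default_rule(spec$d, options$seed)
  if (rule$method == "grid" && spec$d > 2L) {
    stop("dense-grid rule only supported for d <= 2", call. = FALSE)
  }
  fixed_rule <- spec$d == 0L || rule$method %in% c("gh", "qmc")
  std <- if (spec$d > 0L && rule$method %in% c("gh", "qmc")) {
    standardized_points(rule, spec$d)
  } else NULL

  theta0 <- if (is.null(start)) {
    pack_parameters(spec, initial_values(data, spec))
  } else start
  stopifnot(length(theta0) == nrow(frame$pidx))

  nev <- 0L
  # one fused evaluation per point: nlminb asks for the objective and the
  # gradient at the same theta back-to-back, so both come from one kernel
  # pass (the gradient is nearly free once the likelihood is evaluated)
  cache <- new.env(parent = emptyenv())
  full_eval <- function(th) {
    if (!is.null(cache$theta) && identical(th, cache$theta)) {
      return(cache$res)
    }
    nev <<- nev + 1L
    res <- loglik_core(th, frame, rule, std = std, want_grad = fixed_rule)
    cache$theta <- th
    cache$res <- res
    res
  }
  objective <- function(th) -full_eval(th)$ll
  gradient <- if (fixed_rule) {
    function(th) -full_eval(th)$gradient
  } else {
    function(th) {
      -vapply(seq_along(th), function(i) {
        h <- max(1e-5, 1e-5 * abs(th[i]))
        tp <- th; tm <- th
        tp[i] <- th[i] + h; tm[i] <- th[i] - h
        (loglik_core(tm, frame, rule, std = std)$ll -
            loglik_core(tp, frame, rule, std = std)$ll) / (-2 * h)
      }, 0.0)
    }
  }

  ctrl <- list(iter.max = options$max_iter,
               eval.max = 4L * options$max_iter,
               rel.tol = min(1e-10, options$loglik_tol))
  opt <- stats::nlminb(theta0, objective, gradient, control = ctrl)
  iterations <- opt$iterations
  g <- gradient(opt$par)
  H <- NULL  # Hessian of the negative loglik = observed information
  if (max(abs(g)) > options$grad_tol && fixed_rule) {
    # Newton polish: nlminb's relative-change criterion can stop short of
    # the gradient tolerance; a few damped Newton steps with the
    # finite-difference Hessian of the analytic gradient close the gap.
    # The polish moves theta by O(|g| / curvature), so the cached Hessian
    # remains valid for the standard errors.
    H <- tryCatch({
      J <- num_jacobian(gradient, opt$par)
      (J + t(J)) / 2
    }, error = function(e) NULL)
    if (!is.null(H)) {
      par <- opt$par
      fval <- opt$objective
      for (it in seq_len(20L)) {
        if (max(abs(g)) <= options$grad_tol) break
        step <- tryCatch(
          -solve(H + diag(1e-8, nrow(H)), g),
          error = function(e) NULL
        )
        if (is.null(step)) break
        lam <- 1
        moved <- FALSE
        for (half in seq_len(20L)) {
          cand <- par + lam * step
          fc <- objective(cand)
          if (is.finite(fc) && fc <= fval + 1e-12) {
            par <- cand; fval <- fc; moved <- TRUE
            break
          }
          lam <- lam / 2
        }
        if (!moved) break
        iterations <- iterations + 1L
        g <- gradient(par)
      }
      opt$par <- par
      opt$objective <- fval
    }
  } else if (max(abs(g)) > options$grad_tol) {
    tries <- 0L
    while (max(abs(g)) > options$grad_tol && tries < options$restarts) {
      tries <- tries + 1L
      opt2 <- stats::nlminb(opt$par, objective, gradient, control = ctrl)
      iterations <- iterations + opt2$iterations
      if (opt2$objective <= opt$objective) opt <- opt2
      g <- gradient(opt$par)
    }
  }

  final <- loglik_core(opt$par, frame, rule, std = std)
  params <- unpack_parameters(spec, opt$par)
  ll0 <- loglik_core(theta0, frame, rule, std = std)$ll
  converged <- is.finite(final$ll) && max(abs(g)) <= options$grad_tol
  chol_diag <- frame$pidx$pos[frame$pidx$type == "chol" &
                                frame$pidx$row == frame$pidx$col]
  boundary <- spec$d > 0L && any(abs(opt$par[chol_diag]) > 10)

  fit <- structure(
    list(
      spec = spec, options = options, rule = rule,
      theta = opt$par, params = params,
      loglik = final$ll, ll_subject = final$ll_subject,
      loglik_start = ll0, start = theta0,
      converged = converged, iterations = iterations,
      evaluations = nev, gradient_norm = max(abs(g)),
      violations = final$violations,
      boundary_invalid = converged && final$violations > 0L,
      variance_boundary = boundary,
      Sigma = params$Sigma, re_sds = params$sds, re_cor = params$cor,
      n_subjects = frame$nsubj, n_cells = length(frame$y),
      time_range = frame$time_range,
      seed = options$seed,
      frame = frame, std = std, info_cache = H,
      vcov = NULL, se = NULL
    ),
    class = "mvord_fit"
  )
  if (options$se) fit <- standard_errors(fit)
  fit
}

#' Observed-information standard errors
#'
#' The observed information is the negative Hessian of the marginal
#' log-likelihood at the optimum, computed by central finite differences of
#' the analytic gradient on the unconstrained scale; its inverse is the
#' covariance of the estimates. Standard errors for thresholds,
#' random-effect standard deviations and correlations follow by the delta
#' method through the respective transforms. A non-invertible information
#' matrix flags the standard errors as undefined without rejecting the fit.
#'
#' @param fit An `mvord_fit` object.
#' @return The fit, with `$vcov`, `$se`, `$coef_table`, `$re_sd_table` and
#'   `$re_cor_se` filled in.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "mvord_fit"))
  frame <- fit$frame
  rule <- fit$rule
  std <- fit$std
  fixed_rule <- fit$spec$d == 0L || rule$method %in% c("gh", "qmc")
  theta <- fit$theta
  p <- length(theta)

  H <- matrix(NA_real_, p, p)
  ok <- TRUE
  if (!is.null(fit$info_cache)) {
    H <- fit$info_cache  # negative-loglik Hessian from the Newton polish
  } else if (fixed_rule) {
    gfun <- function(th) loglik_core(th, frame, rule, std = std,
                                     want_grad = TRUE)$gradient
    J <- tryCatch(num_jacobian(gfun, theta), error = function(e) NULL)
    if (is.null(J)) ok <- FALSE else H <- -(J + t(J)) / 2
  } else {
    f <- function(th) loglik_core(th, frame, rule, std = std)$ll
    Hn <- tryCatch(pracma::hessian(f, theta), error = function(e) NULL)
    if (is.null(Hn)) ok <- FALSE else H <- -(Hn + t(Hn)) / 2
  }
  V <- NULL
  if (ok) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(diag(V) < 0)) {
      # keep the matrix but flag undefined entries through NA SEs
      diag(V)[diag(V) < 0] <- NA_real_
    }
  }
  fit$information <- H
  fit$vcov <- V
  fit$se <- if (is.null(V)) rep(NA_real_, p) else sqrt(pmax(diag(V), 0))
  fit$se_defined <- !is.null(V)
  fit$coef_table <- build_coef_table(fit)
  re <- build_re_tables(fit)
  fit$re_sd_table <- re$sd_table
  fit$re_cor_se <- re$cor_se
  fit
}

#' @keywords internal
comparison_label <- function(c, C1) {
  paste0(paste(0:c, collapse = ","), " vs ",
         paste((c + 1):(C1 - 1L), collapse = ","))
}

# Coefficient table on the natural scale: thresholds via the delta method
# through the increasing-threshold transform, coefficients as-is.
#' @keywords internal
build_coef_table <- function(fit) {
  spec <- fit$spec
  pidx <- fit$frame$pidx
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  V <- fit$vcov
  rows <- list()
  for (k in seq_len(spec$K)) {
    nm <- onames[k]
    C1 <- spec$outcomes[[k]]$n_categories
    C <- C1 - 1L
    tpos <- pidx$pos[pidx$type == "threshold_raw" & pidx$outcome == nm]
    thr <- fit$params$thresholds[[nm]]
    se_thr <- rep(NA_real_, C)
    if (!is.null(V)) {
      J <- matrix(0, C, C)  # d thr_c / d raw_j
      J[, 1] <- 1
      if (C > 1L) {
        raw <- fit$theta[tpos]
        for (j in 2:C) J[j:C, j] <- exp(raw[j])
      }
      Vt <- J %*% V[tpos, tpos, drop = FALSE] %*% t(J)
      se_thr <- sqrt(pmax(diag(Vt), 0))
      se_thr[diag(Vt) < 0 | is.na(diag(Vt))] <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      term = "intercept", outcome = nm,
      cutpoint_comparison = vapply(0:(C - 1L), comparison_label, "",
                                   C1 = C1),
      estimate = thr, se = se_thr, stringsAsFactors = FALSE
    )
    for (tm in spec$terms) {
      cpos <- pidx$pos[pidx$type == "coef" & pidx$outcome == nm &
                        pidx$term == tm]
      cp <- pidx$cutpoint[match(cpos, pidx$pos)]
      lab <- if (all(is.na(cp))) "shared" else
        vapply(cp, comparison_label, "", C1 = C1)
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm, outcome = nm, cutpoint_comparison = lab,
        estimate = fit$theta[cpos],
        se = if (is.null(V)) NA_real_ else fit$se[cpos],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  rownames(out) <- NULL
  out[, c("term", "outcome", "cutpoint_comparison", "estimate", "se",
          "z", "p")]
}

# Delta-method SEs for random-effect SDs and correlations through the
# Cholesky transform.
#' @keywords internal
build_re_tables <- function(fit) {
  spec <- fit$spec
  d <- spec$d
  if (d == 0L) return(list(sd_table = NULL, cor_se = NULL))
  pidx <- fit$frame$pidx
  cpos <- pidx$pos[pidx$type == "chol"]
  mask <- fit$frame$mask
  labs <- re_labels(spec)
  trans <- function(cp) {
    cv <- covariance_from_cholesky(cp, d, mask)
    lt <- lower.tri(cv$cor)
    c(cv$sds, cv$cor[lt])
  }
  vals <- trans(fit$theta[cpos])
  se <- rep(NA_real_, length(vals))
  if (!is.null(fit$vcov)) {
    Vc <- fit$vcov[cpos, cpos, drop = FALSE]
    if (!anyNA(Vc)) {
      J <- num_jacobian(trans, fit$theta[cpos])
      Vt <- J %*% Vc %*% t(J)
      se <- sqrt(pmax(diag(Vt), 0))
      se[diag(Vt) < 0] <- NA_real_
    }
  }
  sd_table <- data.frame(effect = labs, sd = vals[seq_len(d)],
                         se = se[seq_len(d)], stringsAsFactors = FALSE)
  cor_se <- matrix(NA_real_, d, d, dimnames = list(labs, labs))
  lt <- lower.tri(cor_se)
  cor_se[lt] <- se[-seq_len(d)]
  cor_se[upper.tri(cor_se)] <- t(cor_se)[upper.tri(cor_se)]
  list(sd_table = sd_table, cor_se = cor_se)
}

#' @keywords internal
re_labels <- function(spec) {
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  suff <- cap1(spec$time)
  labs <- character(spec$d)
  for (k in seq_len(spec$K)) {
    if (!is.na(spec$re_int_col[k])) {
      labs[spec$re_int_col[k]] <- paste0(onames[k], "Int")
    }
    if (!is.na(spec$re_slope_col[k])) {
      labs[spec$re_slope_col[k]] <- paste0(onames[k], suff)
    }
  }
  labs
}

#' Random-effect correlation matrix of a fit
#'
#' The correlation matrix of the fitted 2K-dimensional random effects,
#' labelled `<outcome>Int` / `<outcome><Time>` and ordered intercept then
#' slope within outcome, with delta-method standard errors in the
#' `"se"` attribute when available.
#'
#' @param fit A converged `mvord_fit` with d >= 2.
#' @return Labelled correlation matrix.
#' @export
re_correlation <- function(fit) {
  stopifnot(inherits(fit, "mvord_fit"))
  if (fit$spec$d < 2L) {
    stop("random-effect correlation requires d >= 2", call. = FALSE)
  }
  m <- fit$re_cor
  labs <- re_labels(fit$spec)
  dimnames(m) <- list(labs, labs)
  attr(m, "se") <- fit$re_cor_se
  m
}

#' @export
logLik.mvord_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = object$n_cells, class = "logLik")
}

#' @export
coef.mvord_fit <- function(object, ...) {
  stats::setNames(object$theta, object$frame$pidx$label)
}

#' @export
vcov.mvord_fit <- function(object, ...) object$vcov

#' @export
print.mvord_fit <- function(x, ...) {
  cat("Multivariate mixed cumulative logit model fit\n")
  cat(sprintf("  subjects: %d   observed cells: %d   parameters: %d\n",
              x$n_subjects, x$n_cells, length(x$theta)))
  cat(sprintf("  integration: %s%s   seed: %d\n", x$rule$method,
              if (x$rule$method == "qmc") sprintf(" (%d points)",
                                                  x$rule$points)
              else sprintf(" (%d nodes/dim)", x$rule$nodes),
              x$seed))
  cat(sprintf("  log-likelihood: %.4f   %s (%d iterations, |grad| %.2e)\n",
              x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations, x$gradient_norm))
  if (x$violations > 0) {
    cat(sprintf("  WARNING: %d design cell(s) with crossed cutpoints%s\n",
                x$violations,
                if (x$boundary_invalid) " (fit flagged boundary-invalid)"
                else ""))
  }
  invisible(x)
}

#' @export
summary.mvord_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$coef_table)) {
    cat("\nCoefficients:\n")
    print(object$coef_table, digits = 4, row.names = FALSE)
  }
  if (object$spec$d >= 2L) {
    cat("\nRandom-effect standard deviations:\n")
    print(object$re_sd_table, digits = 4, row.names = FALSE)
    cat("\nRandom-effect correlations:\n")
    print(round(re_correlation(object), 3))
  }
  invisible(object)
}
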