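# Inference on the proportional odds assumption and predicted cumulative
# probability curves.

#' Likelihood-ratio test of the proportional odds assumption
#'
#' Compares a (partial) proportional odds fit against the non-proportional
#' fit it is nested in: statistic 2 (llik_NPO - llik_PO) clipped at 0,
#' chi-squared reference with degrees of freedom equal to the parameter
#' count difference. The fits must use identical integration settings
#' (otherwise their log-likelihoods are not comparable) and both must have
#' converged.
#'
#' @param fit_npo,fit_po `mvord_fit` objects with nested specifications.
#' @return An object of class `mvord_test` with `statistic`, `df`,
#'   `p_value`, `kind = "lrt"`.
#' @export
lrt_proportional_odds <- function(fit_npo, fit_po) {
  stopifnot(inherits(fit_npo, "mvord_fit"), inherits(fit_po, "mvord_fit"))
  if (!specs_nested(fit_po$spec, fit_npo$spec)) {
    stop("specifications are not nested", call. = FALSE)
  }
  if (!identical(fit_po$rule[c("method", "nodes", "points", "seed")],
                 fit_npo$rule[c("method", "nodes", "points", "seed")])) {
    stop("fits use different integration settings; log-likelihoods are ",
         "not comparable", call. = FALSE)
  }
  if (!fit_po$converged || !fit_npo$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  df <- length(fit_npo$theta) - length(fit_po$theta)
  if (df < 1L) {
    # identical specifications: degenerate test
    stat <- max(0, 2 * (fit_npo$loglik - fit_po$loglik))
    return(structure(list(statistic = stat, df = 0L, p_value = 1,
                          kind = "lrt",
                          null = "proportional odds",
                          alternative = "non-proportional odds"),
                     class = "mvord_test"))
  }
  stat <- max(0, 2 * (fit_npo$loglik - fit_po$loglik))
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         kind = "lrt", null = "proportional odds",
         alternative = "non-proportional odds"),
    class = "mvord_test"
  )
}

#' Wald test of coefficient homogeneity across cutpoints
#'
#' For a cutpoint-specific term of one outcome, tests the proportional odds
#' restriction that all C copies are equal, using the C - 1 consecutive
#' difference contrasts and the fitted covariance of the estimates.
#'
#' @param fit An `mvord_fit` with standard errors available.
#' @param term Term name (must be `per_cutpoint` for `outcome`).
#' @param outcome Outcome name.
#' @return An `mvord_test` with `statistic`, `df = C - 1`, `p_value`,
#'   `kind = "wald"`.
#' @export
wald_homogeneity <- function(fit, term, outcome) {
  stopifnot(inherits(fit, "mvord_fit"))
  if (is.null(fit$vcov)) stop("fit has no covariance matrix; run ",
                              "standard_errors() first", call. = FALSE)
  pidx <- fit$frame$pidx
  pos <- pidx$pos[pidx$type == "coef" & pidx$outcome == outcome &
                    pidx$term == term]
  if (length(pos) < 2L) {
    stop("term '", term, "' is not cutpoint-specific for outcome '",
         outcome, "'", call. = FALSE)
  }
  C <- length(pos)
  D <- matrix(0, C - 1L, length(fit$theta))
  for (i in seq_len(C - 1L)) {
    D[i, pos[i]] <- 1
    D[i, pos[i + 1L]] <- -1
  }
  dv <- D %*% fit$theta
  Vd <- D %*% fit$vcov %*% t(D)
  if (anyNA(Vd)) stop("undefined standard errors for term '", term, "'",
                      call. = FALSE)
  stat <- drop(t(dv) %*% solve(Vd, dv))
  structure(
    list(statistic = stat, df = C - 1L,
         p_value = stats::pchisq(stat, C - 1L, lower.tail = FALSE),
         kind = "wald", term = term, outcome = outcome,
         null = "equal coefficients across cutpoints",
         alternative = "cutpoint-specific coefficients"),
    class = "mvord_test"
  )
}

#' @export
print.mvord_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, df = %d, p = %.4g\n",
              toupper(x$kind), x$statistic, x$df, x$p_value))
  cat(sprintf("  H0: %s   H1: %s\n", x$null, x$alternative))
  invisible(x)
}

#' Prediction grid for cumulative probability curves
#'
#' @param covariates Named list of covariate values; the full factorial
#'   combination defines one curve set per row (e.g.
#'   `list(gender = c(0, 1))`).
#' @param times Numeric vector of time values at which to evaluate.
#' @param average If `TRUE`, curves marginalize over the fitted
#'   random-effect distribution (population-averaged); default conditions
#'   on w = 0 (the median subject).
#' @param allow_extrapolation Permit time values outside the observed
#'   range.
#' @return An object of class `prediction_grid`.
#' @export
prediction_grid <- function(covariates = list(), times, average = FALSE,
                            allow_extrapolation = FALSE) {
  structure(
    list(covariates = covariates, times = times, average = isTRUE(average),
         allow_extrapolation = isTRUE(allow_extrapolation)),
    class = "prediction_grid"
  )
}

#' Predicted cumulative probability curves
#'
#' For each outcome, covariate setting, time point and cutpoint c, the
#' probability of use at level c + 1 or above, 1 - P(Y <= c): the highest
#' curve is "any use" (c = 0) and the lowest "daily or near-daily use"
#' (c = C - 1). Conditional curves plug w = 0 into the linear predictor;
#' population-averaged curves integrate the logistic over the fitted
#' normal distribution of the relevant random intercept + slope
#' combination (41-node Gauss-Hermite), which attenuates them toward 0.5.
#'
#' @param fit A converged `mvord_fit`.
#' @param grid A [prediction_grid()].
#' @return A data frame: `outcome`, covariate columns, `time`, `cutpoint`,
#'   `comparison`, `probability`, `variant`.
#' @export
predict_cumulative_curves <- function(fit, grid) {
  stopifnot(inherits(fit, "mvord_fit"), inherits(grid, "prediction_grid"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  spec <- fit$spec
  tr <- fit$time_range
  if (!grid$allow_extrapolation &&
      (min(grid$times) < tr[1] - 1e-9 || max(grid$times) > tr[2] + 1e-9)) {
    stop("prediction times outside the observed range [",
         tr[1], ", ", tr[2], "]; set allow_extrapolation = TRUE",
         call. = FALSE)
  }
  settings <- if (length(grid$covariates)) {
    expand.grid(grid$covariates, KEEP.OUT.ATTRS = FALSE)
  } else data.frame(.dummy = 0)
  gh <- gh_nodes(41L)
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  out <- list()
  for (k in seq_len(spec$K)) {
    nm <- onames[k]
    C1 <- spec$outcomes[[k]]$n_categories
    C <- C1 - 1L
    thr <- fit$params$thresholds[[nm]]
    for (s in seq_len(nrow(settings))) {
      for (tv in grid$times) {
        row <- settings[s, , drop = FALSE]
        row[[spec$time]] <- tv
        x <- vapply(spec$terms, function(tm) term_values(row, tm), 0.0)
        for (c in 0:(C - 1L)) {
          b <- vapply(seq_along(spec$terms), function(j) {
            bj <- fit$params$beta[[nm]][[spec$terms[j]]]
            if (length(bj) == 1L) bj else bj[c + 1L]
          }, 0.0)
          eta <- thr[c + 1L] + if (length(x)) sum(x * b) else 0
          if (grid$average && spec$d > 0L) {
            ic <- spec$re_int_col[k]
            sc <- spec$re_slope_col[k]
            v <- 0
            if (!is.na(ic)) v <- v + fit$Sigma[ic, ic]
            if (!is.na(sc)) v <- v + tv^2 * fit$Sigma[sc, sc]
            if (!is.na(ic) && !is.na(sc)) v <- v + 2 * tv *
                fit$Sigma[ic, sc]
            s_re <- sqrt(max(v, 0))
            ple <- sum(gh$w / sqrt(pi) *
                         stats::plogis(eta + sqrt(2) * s_re * gh$x))
          } else {
            ple <- stats::plogis(eta)
          }
          out[[length(out) + 1L]] <- cbind(
            data.frame(outcome = nm, stringsAsFactors = FALSE),
            settings[s, setdiff(names(settings), ".dummy"), drop = FALSE],
            data.frame(time = tv, cutpoint = c,
                       comparison = comparison_label(c, C1),
                       probability = 1 - ple,
                       variant = if (grid$average) "averaged" else
                         "conditional",
                       stringsAsFactors = FALSE)
          )
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
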