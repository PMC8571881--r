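# Likelihood engine: conditional category probabilities and the marginal
# log-likelihood integrated over the random effects.

#' Logistic cumulative probability
#'
#' Inverse of the cumulative logit link: `1 / (1 + exp(-eta))`, numerically
#' stable in both tails.
#'
#' @param eta Numeric vector of cumulative logits.
#' @return Probabilities P(Y <= c).
#' @export
cumulative_probability <- function(eta) stats::plogis(eta)

#' Category probabilities from cumulative probabilities
#'
#' Differences adjacent cumulative probabilities into a category pmf:
#' p(0) = P(Y<=0), p(c) = P(Y<=c) - P(Y<=c-1), p(C) = 1 - P(Y<=C-1).
#' Under a non-proportional odds parameterization cumulative curves can
#' cross away from the reference covariate point, producing a non-positive
#' difference; such entries are floored at 1e-10 and the number of floored
#' entries is recorded in the `"violations"` attribute (never hidden).
#'
#' @param cum_probs Numeric vector of C values P(Y <= c), each in (0, 1).
#' @return Numeric vector of C + 1 category probabilities.
#' @export
category_pmf <- function(cum_probs) {
  if (any(cum_probs <= 0 | cum_probs >= 1)) {
    stop("cumulative probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  p <- diff(c(0, cum_probs, 1))
  viol <- sum(p <= 0)
  if (viol) p <- pmax(p, 1e-10)
  structure(p, violations = viol)
}

#' Conditional log-likelihood of one subject given its random effects
#'
#' Sum over the subject's outcomes and occasions with a non-missing
#' category of the log conditional category probability at random-effect
#' value `w`; missing cells contribute nothing (missing at random given
#' covariates and random effects), and a subject with no observed cells
#' returns 0.
#'
#' @param data An `mvord_data` object.
#' @param spec An [mvord_spec()].
#' @param params Packed parameter vector or `mvord_params` list.
#' @param subject Subject identifier (as in the data).
#' @param w Numeric random-effect vector of length `spec$d`.
#' @return The conditional log-likelihood (scalar).
#' @export
conditional_loglik_subject <- function(data, spec, params, subject,
                                       w = numeric(spec$d)) {
  stopifnot(length(w) == spec$d)
  if (is.numeric(params)) params <- unpack_parameters(spec, params)
  frame <- build_frame(data, spec)
  sidx <- match(subject, frame$subjects)
  if (is.na(sidx)) stop("unknown subject: ", subject, call. = FALSE)
  sel <- which(frame$subj0 == sidx - 1L)
  if (!length(sel)) return(0)
  et <- frame_eta(frame, params)
  off <- numeric(length(sel))
  for (i in seq_along(sel)) {
    m <- sel[i]
    if (frame$icol0[m] >= 0L) off[i] <- off[i] + w[frame$icol0[m] + 1L]
    if (frame$scol0[m] >= 0L) off[i] <- off[i] + w[frame$scol0[m] + 1L] *
        frame$t[m]
  }
  up <- et$eta_up[sel] + off
  lo <- et$eta_lo[sel] + off
  p <- ifelse(is.infinite(up), 1, stats::plogis(up)) -
    ifelse(is.infinite(lo), 0, stats::plogis(lo))
  sum(log(pmax(p, 1e-10)))
}

#' Marginal log-likelihood
#'
#' Sum over subjects of the log of the conditional likelihood integrated
#' over the random-effect distribution MVN(0, Sigma_w), computed with the
#' chosen [integration_rule()] and log-sum-exp accumulation. With d = 0 the
#' integral degenerates to the conditional log-likelihood.
#'
#' @param data An `mvord_data` object.
#' @param spec An [mvord_spec()].
#' @param params Packed parameter vector or `mvord_params` list.
#' @param rule An [integration_rule()]; default chosen by dimension.
#' @return The marginal log-likelihood, with attributes `ll_subject`
#'   (per-subject contributions) and `violations` (count of design cells
#'   with crossed cutpoints).
#' @export
marginal_loglik <- function(data, spec, params, rule = NULL) {
  if (!is.numeric(params)) params <- pack_parameters(spec, params)
  rule <- rule %||% default_rule(spec$d)
  frame <- build_frame(data, spec)
  res <- loglik_core(params, frame, rule)
  structure(res$ll, ll_subject = res$ll_subject,
            violations = res$violations)
}

#' Gradient of the marginal log-likelihood
#'
#' For the fixed-point rules (`gh`, `qmc`) the default is the exact
#' analytic gradient of the rule's approximation (chain rule through the
#' threshold and Cholesky transforms). `method = "numeric"` computes
#' central finite differences with per-coordinate step
#' `max(1e-5, 1e-5 |theta|)`; the standardized point set is built once and
#' reused across all perturbations (common random numbers), and it is the
#' only gradient available for the adaptive rule.
#'
#' @inheritParams marginal_loglik
#' @param method `"analytic"` or `"numeric"`.
#' @return Numeric gradient vector over the packed parameters.
#' @export
loglik_gradient <- function(data, spec, params, rule = NULL,
                            method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (!is.numeric(params)) params <- pack_parameters(spec, params)
  rule <- rule %||% default_rule(spec$d)
  frame <- build_frame(data, spec)
  if (method == "analytic") {
    return(loglik_core(params, frame, rule, want_grad = TRUE)$gradient)
  }
  std <- if (spec$d > 0L && rule$method %in% c("gh", "qmc")) {
    standardized_points(rule, spec$d)
  } else NULL
  f <- function(th) loglik_core(th, frame, rule, std = std)$ll
  g <- numeric(length(params))
  for (i in seq_along(params)) {
    h <- max(1e-5, 1e-5 * abs(params[i]))
    for (try in 1:3) {
      tp <- params; tm <- params
      tp[i] <- params[i] + h
      tm[i] <- params[i] - h
      fp <- f(tp); fm <- f(tm)
      if (is.finite(fp) && is.finite(fm)) {
        g[i] <- (fp - fm) / (2 * h)
        break
      }
      h <- h / 10
      if (try == 3) stop("non-finite log-likelihood at perturbed parameter ",
                         i, call. = FALSE)
    }
  }
  g
}

# Structural nesting: spec_po shares (a subset of) the coefficients that
# spec_npo frees per cutpoint; everything else identical.
#' @keywords internal
specs_nested <- function(spec_po, spec_npo) {
  same_out <- identical(
    lapply(spec_po$outcomes, function(o) o[c("name", "n_categories")]),
    lapply(spec_npo$outcomes, function(o) o[c("name", "n_categories")])
  )
  if (!same_out) return(FALSE)
  if (!identical(spec_po$terms, spec_npo$terms)) return(FALSE)
  if (!identical(spec_po$random, spec_npo$random)) return(FALSE)
  if (!identical(spec_po$time, spec_npo$time)) return(FALSE)
  all(spec_po$prop == spec_npo$prop |
        (spec_po$prop == "shared" & spec_npo$prop == "per_cutpoint"))
}

#' Embed a proportional-odds parameter vector in a non-proportional space
#'
#' A (partial) proportional odds model is a linear restriction of the
#' non-proportional model: copying each shared coefficient into all C
#' cutpoint slots yields a parameter vector for the larger specification
#' with an identical likelihood.
#'
#' @param params_po Packed parameter vector for `spec_po`.
#' @param spec_po,spec_npo Nested specifications (`spec_po` restricted).
#' @return Packed parameter vector for `spec_npo`.
#' @export
expand_po_to_npo <- function(params_po, spec_po, spec_npo) {
  if (!specs_nested(spec_po, spec_npo)) {
    stop("specifications are not nested", call. = FALSE)
  }
  p <- unpack_parameters(spec_po, params_po)
  onames <- vapply(spec_po$outcomes, `[[`, "", "name")
  for (k in seq_len(spec_po$K)) {
    nm <- onames[k]
    C <- spec_po$outcomes[[k]]$n_categories - 1L
    for (tm in spec_po$terms) {
      if (spec_po$prop[k, tm] == "shared" &&
          spec_npo$prop[k, tm] == "per_cutpoint") {
        p$beta[[nm]][[tm]] <- rep(p$beta[[nm]][[tm]], C)
      }
    }
  }
  pack_parameters(spec_npo, p)
}

#' Restrict a non-proportional parameter vector to a nested PO space
#'
#' Inverse of [expand_po_to_npo()] for vectors whose cutpoint copies are
#' equal (averaging otherwise).
#'
#' @param params_npo Packed parameter vector for `spec_npo`.
#' @param spec_po,spec_npo Nested specifications.
#' @return Packed parameter vector for `spec_po`.
#' @export
restrict_npo_to_po <- function(params_npo, spec_po, spec_npo) {
  if (!specs_nested(spec_po, spec_npo)) {
    stop("specifications are not nested", call. = FALSE)
  }
  p <- unpack_parameters(spec_npo, params_npo)
  onames <- vapply(spec_po$outcomes, `[[`, "", "name")
  for (k in seq_len(spec_po$K)) {
    nm <- onames[k]
    for (tm in spec_po$terms) {
      if (spec_po$prop[k, tm] == "shared" &&
          spec_npo$prop[k, tm] == "per_cutpoint") {
        p$beta[[nm]][[tm]] <- mean(p$beta[[nm]][[tm]])
      }
    }
  }
  pack_parameters(spec_po, p)
}
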