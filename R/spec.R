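# Model specification: fixed-effect structure (shared vs cutpoint-specific
# coefficients per outcome), random-effects structure, and the bijection
# between structured parameters and the unconstrained optimization vector.

#' Random-effects structure
#'
#' Each outcome can carry a random intercept and/or a random slope on the
#' time variable; stacking them outcome by outcome gives the random-effect
#' vector W_i of dimension d <= 2K with covariance Sigma_w. With
#' `correlation = "full"` Sigma_w is unstructured, so effects are correlated
#' across outcomes (the inter-outcome association of interest); with
#' `"block_diagonal"` cross-outcome blocks are structurally zero and the
#' model decouples into K univariate models.
#'
#' @param intercept,slope Logical, recycled over outcomes.
#' @param correlation `"full"` or `"block_diagonal"`.
#' @return An object of class `random_structure`.
#' @export
random_structure <- function(intercept = TRUE, slope = TRUE,
                             correlation = c("full", "block_diagonal")) {
  correlation <- match.arg(correlation)
  structure(
    list(intercept = intercept, slope = slope, correlation = correlation),
    class = "random_structure"
  )
}

#' Specify a multivariate mixed cumulative logit model
#'
#' Declares, for each ordinal outcome, which covariate coefficients are
#' shared across the C cumulative logits (proportional odds) and which are
#' cutpoint-specific (non-proportional odds); mixing the two gives a partial
#' proportional odds model. Thresholds (the cutpoint intercepts) are always
#' cutpoint-specific and kept increasing by construction. The linear
#' predictor for outcome k, cutpoint c is
#' `logit P(Y <= c) = thr_c^k + sum_t x_t beta_tc^k + nu_i^k + mu_i^k t_ij`,
#' so a positive coefficient shifts mass toward lower categories.
#'
#' @param outcomes List of [outcome_def()] objects (or a single one).
#' @param fixed Named character vector mapping term names to `"shared"` or
#'   `"per_cutpoint"`, applied to every outcome; or a named list with one
#'   such vector per outcome (names matching outcome names). Interaction
#'   terms are written `"a:b"`.
#' @param random A [random_structure()].
#' @param time Name of the time variable (enters the random slope; usually
#'   also one of the fixed terms).
#' @return An object of class `mvord_spec`.
#' @export
mvord_spec <- function(outcomes, fixed = character(),
                       random = random_structure(), time = "age") {
  if (inherits(outcomes, "outcome_def")) outcomes <- list(outcomes)
  stopifnot(length(outcomes) >= 1L, inherits(random, "random_structure"))
  K <- length(outcomes)
  onames <- vapply(outcomes, `[[`, "", "name")
  if (anyDuplicated(onames)) stop("duplicate outcome names", call. = FALSE)

  norm1 <- function(v) {
    v <- unlist(v)
    if (length(v) && is.null(names(v))) {
      stop("fixed terms must be named (term = proportionality)",
           call. = FALSE)
    }
    if (anyDuplicated(names(v))) stop("duplicate term: ",
                                      names(v)[duplicated(names(v))][1],
                                      call. = FALSE)
    bad <- setdiff(unname(v), c("shared", "per_cutpoint"))
    if (length(bad)) {
      stop("proportionality must be 'shared' or 'per_cutpoint', got: ",
           bad[1], call. = FALSE)
    }
    v
  }
  if (is.list(fixed) && !is.null(names(fixed)) &&
      all(names(fixed) %in% onames)) {
    per <- lapply(fixed, norm1)
    if (!setequal(names(per), onames)) {
      stop("per-outcome fixed list must name every outcome", call. = FALSE)
    }
    terms <- names(per[[onames[1]]])
    for (k in onames) {
      if (!identical(names(per[[k]]), terms)) {
        stop("every outcome must use the same term set (in the same order)",
             call. = FALSE)
      }
    }
    prop <- do.call(rbind, per[onames])
  } else {
    v <- norm1(fixed)
    terms <- names(v) %||% character(0)
    prop <- matrix(rep(unname(v), each = K), nrow = K,
                   dimnames = list(onames, terms))
  }
  if ("intercept" %in% terms) {
    stop("intercepts are the thresholds and are always cutpoint-specific; ",
         "do not list 'intercept' as a term", call. = FALSE)
  }

  ri <- rep_len(random$intercept, K)
  rs <- rep_len(random$slope, K)
  # w-column index (1-based) of each outcome's intercept / slope effect
  icol <- scol <- rep(NA_integer_, K)
  d <- 0L
  for (k in seq_len(K)) {
    if (ri[k]) { d <- d + 1L; icol[k] <- d }
    if (rs[k]) { d <- d + 1L; scol[k] <- d }
  }
  spec <- structure(
    list(outcomes = outcomes, terms = terms, prop = prop,
         random = random, time = time,
         K = K, d = d, re_int_col = icol, re_slope_col = scol),
    class = "mvord_spec"
  )
  spec$pidx_cache <- parameter_index(spec)
  spec
}

#' @export
print.mvord_spec <- function(x, ...) {
  cat("Multivariate mixed cumulative logit model specification\n")
  for (k in seq_len(x$K)) {
    od <- x$outcomes[[k]]
    cat(sprintf("  %s (%d categories):", od$name, od$n_categories))
    if (length(x$terms)) {
      cat(" ", paste(sprintf("%s[%s]", x$terms, x$prop[k, ]),
                     collapse = " + "))
    } else cat(" thresholds only")
    cat("\n")
  }
  cat(sprintf("  random effects: d = %d (%s), time = '%s'\n",
              x$d, x$random$correlation, x$time))
  cat(sprintf("  parameters: %d\n", nrow(parameter_index(x))))
  invisible(x)
}

# Lower-triangular Cholesky mask: full, or block-diagonal per outcome.
#' @keywords internal
chol_mask <- function(spec) {
  d <- spec$d
  if (d == 0L) return(matrix(logical(0), 0, 0))
  block <- integer(d)
  for (k in seq_len(spec$K)) {
    if (!is.na(spec$re_int_col[k])) block[spec$re_int_col[k]] <- k
    if (!is.na(spec$re_slope_col[k])) block[spec$re_slope_col[k]] <- k
  }
  m <- lower.tri(diag(d), diag = TRUE)
  if (spec$random$correlation == "block_diagonal") {
    m <- m & outer(block, block, `==`)
  }
  m
}

#' Parameter index of a model specification
#'
#' Enumerates the unconstrained parameter vector: per outcome its C raw
#' thresholds (first free, then log-increments), then its fixed-effect
#' coefficients term by term (one slot if shared, C slots if
#' cutpoint-specific), and finally the free entries of the lower-triangular
#' Cholesky factor of Sigma_w (log-transformed diagonal; cross-outcome
#' entries absent under a block-diagonal structure). The map is a bijection
#' between names and positions.
#'
#' @param spec An [mvord_spec()].
#' @return A data frame with columns `pos`, `type` (`threshold_raw`, `coef`,
#'   `chol`), `outcome`, `term`, `cutpoint`, `row`, `col`, `label`.
#' @export
parameter_index <- function(spec) {
  stopifnot(inherits(spec, "mvord_spec"))
  if (!is.null(spec$pidx_cache)) return(spec$pidx_cache)
  rows <- list()
  for (k in seq_len(spec$K)) {
    od <- spec$outcomes[[k]]
    C <- od$n_categories - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      type = "threshold_raw", outcome = od$name, term = "intercept",
      cutpoint = 0:(C - 1L), row = NA_integer_, col = NA_integer_,
      stringsAsFactors = FALSE
    )
    for (tm in spec$terms) {
      if (spec$prop[k, tm] == "shared") {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "coef", outcome = od$name, term = tm,
          cutpoint = NA_integer_, row = NA_integer_, col = NA_integer_,
          stringsAsFactors = FALSE
        )
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "coef", outcome = od$name, term = tm,
          cutpoint = 0:(C - 1L), row = NA_integer_, col = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  m <- chol_mask(spec)
  if (spec$d > 0L) {
    idx <- which(m, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      type = "chol", outcome = NA_character_, term = NA_character_,
      cutpoint = NA_integer_, row = idx[, 1], col = idx[, 2],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$pos <- seq_len(nrow(out))
  out$label <- ifelse(
    out$type == "threshold_raw",
    sprintf("%s:thr[%d]", out$outcome, out$cutpoint),
    ifelse(out$type == "coef",
           ifelse(is.na(out$cutpoint),
                  sprintf("%s:%s", out$outcome, out$term),
                  sprintf("%s:%s[c%d]", out$outcome, out$term,
                          out$cutpoint)),
           sprintf("chol[%d,%d]", out$row, out$col))
  )
  out[, c("pos", "type", "outcome", "term", "cutpoint", "row", "col",
          "label")]
}

#' Number of free parameters of a specification
#' @param spec An [mvord_spec()].
#' @return Integer count.
#' @export
n_parameters <- function(spec) nrow(parameter_index(spec))

#' Increasing thresholds from an unconstrained vector
#'
#' `out[1] = raw[1]`, `out[c] = out[c-1] + exp(raw[c])`: any real vector
#' maps to strictly increasing thresholds, so the optimizer's search space
#' is unconstrained.
#'
#' @param raw Numeric vector of length C.
#' @return Strictly increasing numeric vector of length C.
#' @export
thresholds_from_unconstrained <- function(raw) {
  if (length(raw) == 0L) return(raw)
  if (length(raw) == 1L) return(raw)
  cumsum(c(raw[1], exp(raw[-1])))
}

#' Inverse of [thresholds_from_unconstrained()]
#' @param thresholds Strictly increasing numeric vector.
#' @return Unconstrained vector; exact round trip.
#' @export
unconstrained_from_thresholds <- function(thresholds) {
  if (length(thresholds) <= 1L) return(thresholds)
  d <- diff(thresholds)
  if (any(d <= 0)) stop("thresholds must be strictly increasing",
                        call. = FALSE)
  c(thresholds[1], log(d))
}

#' Random-effect covariance from packed Cholesky parameters
#'
#' Rebuilds the lower-triangular factor L (row-wise packed, log-transformed
#' diagonal) and returns Sigma_w = L L' together with its correlation
#' matrix. Any real input maps to a symmetric positive semidefinite Sigma_w.
#'
#' @param chol_params Numeric vector of packed entries (length d(d+1)/2 for
#'   a full structure, or the within-block count for block-diagonal).
#' @param d Random-effect dimension.
#' @param mask Optional logical d x d lower-triangular inclusion mask
#'   (default: full lower triangle).
#' @return List with `L`, `Sigma`, `sds`, `cor`.
#' @export
covariance_from_cholesky <- function(chol_params, d, mask = NULL) {
  d <- as.integer(d)
  if (d == 0L) {
    return(list(L = matrix(0, 0, 0), Sigma = matrix(0, 0, 0),
                sds = numeric(0), cor = matrix(0, 0, 0)))
  }
  if (is.null(mask)) mask <- lower.tri(diag(d), diag = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  stopifnot(length(chol_params) == nrow(idx))
  L <- matrix(0, d, d)
  L[idx] <- chol_params
  diag(L) <- exp(diag(L))
  Sigma <- L %*% t(L)
  sds <- sqrt(diag(Sigma))
  cor <- diag(1, d)
  if (d > 1L) {
    cor <- Sigma / tcrossprod(sds)
    diag(cor) <- 1
  }
  list(L = L, Sigma = Sigma, sds = sds, cor = cor)
}

# Inverse: packed parameters from a covariance matrix (exact for matrices
# consistent with the mask; used for truth configs and pack()).
#' @keywords internal
cholesky_params_from_cov <- function(Sigma, mask = NULL) {
  d <- nrow(Sigma)
  if (d == 0L) return(numeric(0))
  if (is.null(mask)) mask <- lower.tri(diag(d), diag = TRUE)
  L <- t(chol(Sigma))
  diag(L) <- log(diag(L))
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  L[idx]
}

#' Unpack an unconstrained vector into structured parameters
#'
#' @param spec An [mvord_spec()].
#' @param theta Numeric vector of length [n_parameters()].
#' @return List of class `mvord_params` with per-outcome `thresholds`
#'   (increasing) and `beta` (named list: scalar for shared terms, length-C
#'   vector for cutpoint-specific ones), plus `L`, `Sigma`, `sds`, `cor`.
#' @export
unpack_parameters <- function(spec, theta) {
  pidx <- parameter_index(spec)
  stopifnot(length(theta) == nrow(pidx))
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  thresholds <- list(); beta <- list()
  for (k in seq_len(spec$K)) {
    nm <- onames[k]
    raw <- theta[pidx$type == "threshold_raw" & pidx$outcome == nm]
    thresholds[[nm]] <- thresholds_from_unconstrained(raw)
    bk <- list()
    for (tm in spec$terms) {
      bk[[tm]] <- theta[pidx$type == "coef" & pidx$outcome == nm &
                          pidx$term == tm]
    }
    beta[[nm]] <- bk
  }
  cp <- theta[pidx$type == "chol"]
  cv <- covariance_from_cholesky(cp, spec$d, chol_mask(spec))
  structure(
    list(thresholds = thresholds, beta = beta,
         L = cv$L, Sigma = cv$Sigma, sds = cv$sds, cor = cv$cor),
    class = "mvord_params"
  )
}

#' Pack structured parameters into the unconstrained vector
#'
#' Exact inverse of [unpack_parameters()]: `pack(unpack(theta))` returns
#' `theta` up to floating-point round trip of the threshold and Cholesky
#' transforms.
#'
#' @param spec An [mvord_spec()].
#' @param params An `mvord_params` list (only `thresholds`, `beta` and
#'   either `L` or `Sigma` are consulted).
#' @return Numeric parameter vector.
#' @export
pack_parameters <- function(spec, params) {
  pidx <- parameter_index(spec)
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  theta <- numeric(nrow(pidx))
  for (k in seq_len(spec$K)) {
    nm <- onames[k]
    sel <- pidx$type == "threshold_raw" & pidx$outcome == nm
    theta[pidx$pos[sel]] <-
      unconstrained_from_thresholds(params$thresholds[[nm]])
    for (tm in spec$terms) {
      sel <- pidx$type == "coef" & pidx$outcome == nm & pidx$term == tm
      b <- params$beta[[nm]][[tm]]
      if (length(b) != sum(sel)) {
        stop(sprintf("coefficient '%s' for outcome '%s': expected %d value(s)",
                     tm, nm, sum(sel)), call. = FALSE)
      }
      theta[pidx$pos[sel]] <- b
    }
  }
  if (spec$d > 0L) {
    mask <- chol_mask(spec)
    if (!is.null(params$L)) {
      L <- params$L
      Ld <- L
      diag(Ld) <- log(diag(L))
      idx <- which(mask, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      cp <- Ld[idx]
    } else {
      cp <- cholesky_params_from_cov(params$Sigma, mask)
    }
    theta[pidx$pos[pidx$type == "chol"]] <- cp
  }
  theta
}
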