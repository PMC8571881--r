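# Integration rules for the marginal likelihood. Fixed-point rules
# (standardized Gauss-Hermite, quasi-Monte Carlo, dense-grid oracle) share
# one code path: a standardized point set is frozen per rule and mapped
# through the current Cholesky factor, so the approximate likelihood is a
# smooth exact function of the parameters (common random numbers across all
# evaluations of a fit). The adaptive rule recentres per subject instead.

#' Choose an integration rule for the random-effects integral
#'
#' * `"gh"` — standardized Gauss-Hermite product rule, `nodes` per
#'   dimension, points scaled by the current Cholesky factor of Sigma_w.
#'   Exactly additive over outcomes under a block-diagonal structure.
#' * `"agh"` — adaptive Gauss-Hermite: per-subject mode-and-curvature
#'   recentring (damped Newton, at most 50 steps, tolerance 1e-8, falling
#'   back to prior centering on failure). Most accurate per node; used for
#'   evaluation and verification.
#' * `"qmc"` — randomly shifted Halton sequence mapped through the normal
#'   quantile and the Cholesky factor; `points` total, deterministic given
#'   `seed`. Default for d >= 4 where product rules explode.
#' * `"grid"` — dense trapezoid grid over \[-8 sd, +8 sd\] per dimension;
#'   brute-force oracle, only allowed for d <= 2.
#'
#' @param method One of `"gh"`, `"agh"`, `"qmc"`, `"grid"`.
#' @param nodes Nodes per dimension (`gh`/`agh`/`grid`).
#' @param points Total points (`qmc`).
#' @param seed Integer seed for the QMC shift.
#' @return An object of class `integration_rule`.
#' @export
integration_rule <- function(method = c("gh", "agh", "qmc", "grid"),
                             nodes = 7L, points = 256L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(nodes >= 1L, points >= 1L)
  structure(
    list(method = method, nodes = as.integer(nodes),
         points = as.integer(points), seed = as.integer(seed)),
    class = "integration_rule"
  )
}

# Default rule by random-effect dimension: product GH is affordable up to
# d = 3; beyond that QMC keeps the point count flat.
#' @keywords internal
default_rule <- function(d, seed = 1L) {
  if (d <= 3L) integration_rule("gh", nodes = 7L, seed = seed)
  else integration_rule("qmc", points = 256L, seed = seed)
}

#' @keywords internal
gh_nodes <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w)
}

# Generalized Halton sequence in (0,1)^d with a seed-derived random shift
# modulo 1 (Cranley-Patterson rotation). First `burn` points dropped.
#' @keywords internal
halton_points <- function(n, d, seed = 1L, burn = 20L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53)
  if (d > length(primes)) stop("QMC rule supports at most 16 dimensions",
                               call. = FALSE)
  radical_inverse <- function(i, b) {
    f <- 1 / b
    r <- 0
    while (i > 0) {
      r <- r + f * (i %% b)
      i <- i %/% b
      f <- f / b
    }
    r
  }
  H <- matrix(0, n, d)
  for (j in seq_len(d)) {
    H[, j] <- vapply(burn + seq_len(n), radical_inverse, 0.0, b = primes[j])
  }
  shift <- with_seed(seed, stats::runif(d))
  H <- sweep(H, 2, shift, `+`) %% 1
  # keep strictly inside (0,1) for the normal quantile map
  pmin(pmax(H, 1e-12), 1 - 1e-12)
}

# Standardized point set for a fixed rule, independent of the parameters.
# Returns U (Q x d), base log-weights, and how points map to w-space:
# w = sqrt(2) L U' (gh) or w = L qnorm(U)' (qmc).
#' @keywords internal
standardized_points <- function(rule, d) {
  if (d == 0L) {
    return(list(M = matrix(0, 1, 1), logwt = 0))
  }
  if (rule$method == "gh") {
    gh <- gh_nodes(rule$nodes)
    grid <- as.matrix(expand.grid(rep(list(seq_len(rule$nodes)), d)))
    U <- matrix(gh$x[grid], nrow(grid), d)
    logwt <- rowSums(matrix(log(gh$w)[grid], nrow(grid), d)) -
      d / 2 * log(pi)
    list(M = sqrt(2) * U, logwt = logwt)
  } else if (rule$method == "qmc") {
    Z <- stats::qnorm(halton_points(rule$points, d, rule$seed))
    list(M = Z, logwt = rep(-log(rule$points), rule$points))
  } else {
    stop("standardized_points: not a fixed standardized rule", call. = FALSE)
  }
}

# Dense trapezoid grid in w-space for d <= 2: points and log-weights
# include the MVN prior density, so the same marginal kernel applies.
#' @keywords internal
grid_points <- function(rule, Sigma) {
  d <- nrow(Sigma)
  if (d > 2L) stop("dense-grid oracle only supported for d <= 2",
                   call. = FALSE)
  g <- rule$nodes
  sds <- sqrt(diag(Sigma))
  axes <- lapply(sds, function(s) seq(-8 * s, 8 * s, length.out = g))
  steps <- vapply(axes, function(a) a[2] - a[1], 0.0)
  tw <- lapply(seq_len(d), function(j) {
    w <- rep(steps[j], g)
    w[c(1, g)] <- steps[j] / 2
    w
  })
  W <- as.matrix(expand.grid(axes))
  LW <- as.matrix(expand.grid(lapply(tw, log)))
  Om <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  logphi <- -0.5 * rowSums((W %*% Om) * W) - d / 2 * log(2 * pi) - 0.5 * ld
  list(W = W, logwt = as.vector(rowSums(LW) + logphi))
}

# AGH standardized product grid (U and log product weights).
#' @keywords internal
agh_grid <- function(rule, d) {
  gh <- gh_nodes(rule$nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(rule$nodes)), d)))
  U <- matrix(gh$x[grid], nrow(grid), d)
  loglam <- rowSums(matrix(log(gh$w)[grid], nrow(grid), d))
  list(U = U, loglam = loglam)
}
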