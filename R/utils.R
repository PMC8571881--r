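# Internal numeric helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Central-difference Jacobian of a vector-valued function; step follows the
# max(1e-5, 1e-5 |x|) per-coordinate rule used throughout the package.
#' @keywords internal
num_jacobian <- function(f, x, step = NULL) {
  p <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), p)
  for (i in seq_len(p)) {
    h <- if (is.null(step)) max(1e-5, 1e-5 * abs(x[i])) else step
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# First capital, rest unchanged: "age" -> "Age" for random-effect labels.
#' @keywords internal
cap1 <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}
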