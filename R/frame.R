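# Internal model frame: the long-format data flattened into "cells"
# (subject x occasion x outcome with a non-missing category) plus the
# design information needed to evaluate the marginal likelihood and its
# gradient. Built once per fit.

#' @keywords internal
term_values <- function(df, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  miss <- setdiff(parts, names(df))
  if (length(miss)) {
    stop("term '", term, "' references unknown column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- df[[parts[1]]]
  for (p in parts[-1]) v <- v * df[[p]]
  as.numeric(v)
}

#' @keywords internal
build_frame <- function(data, spec) {
  stopifnot(inherits(data, "mvord_data"), inherits(spec, "mvord_spec"))
  df <- data$data
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  have <- vapply(data$outcomes, `[[`, "", "name")
  miss <- setdiff(onames, have)
  if (length(miss)) {
    stop("spec outcome(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  subjects <- unique(df$subject)
  subj0_row <- match(df$subject, subjects) - 1L

  need_time <- any(!is.na(spec$re_slope_col)) || spec$time %in%
    unlist(strsplit(spec$terms, ":", fixed = TRUE))
  if (need_time && !spec$time %in% names(df)) {
    stop("time variable '", spec$time, "' not found in data", call. = FALSE)
  }
  trow <- if (spec$time %in% names(df)) as.numeric(df[[spec$time]]) else
    rep(0, nrow(df))

  nterm <- length(spec$terms)
  Xrow <- matrix(0, nrow(df), max(nterm, 1L))
  for (j in seq_len(nterm)) Xrow[, j] <- term_values(df, spec$terms[j])

  cells <- list()
  for (k in seq_len(spec$K)) {
    nm <- onames[k]
    y <- df[[nm]]
    keep <- which(!is.na(y) & !is.na(trow))
    if (!length(keep)) next
    cells[[nm]] <- data.frame(
      k = k, y = y[keep], t = trow[keep], subj0 = subj0_row[keep],
      row = keep
    )
  }
  cells <- do.call(rbind, cells)
  ord <- order(cells$subj0)
  cells <- cells[ord, , drop = FALSE]

  icol0 <- ifelse(is.na(spec$re_int_col), -1L, spec$re_int_col - 1L)
  scol0 <- ifelse(is.na(spec$re_slope_col), -1L, spec$re_slope_col - 1L)

  list(
    spec = spec,
    pidx = parameter_index(spec),
    mask = chol_mask(spec),
    subjects = subjects,
    nsubj = length(subjects),
    ncat = vapply(spec$outcomes, `[[`, 0L, "n_categories"),
    k = cells$k,
    y = cells$y,
    t = cells$t,
    subj0 = as.integer(cells$subj0),
    icol0 = icol0[cells$k],
    scol0 = scol0[cells$k],
    X = Xrow[cells$row, , drop = FALSE],
    nterm = nterm,
    time_range = if (need_time) range(trow, na.rm = TRUE) else c(0, 0)
  )
}

# Fixed parts of the two cumulative logits bracketing each cell's category:
# eta_up at cutpoint c = y (Inf for the top category), eta_lo at c = y - 1
# (-Inf for category 0).
#' @keywords internal
frame_eta <- function(frame, params) {
  spec <- frame$spec
  ncell <- length(frame$y)
  eta_up <- rep(Inf, ncell)
  eta_lo <- rep(-Inf, ncell)
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  for (k in seq_len(spec$K)) {
    sel <- which(frame$k == k)
    if (!length(sel)) next
    C <- frame$ncat[k] - 1L
    thr <- params$thresholds[[onames[k]]]
    # coefficient matrix: C rows (cutpoints) x terms, shared rows replicated
    B <- matrix(0, C, max(frame$nterm, 1L))
    for (j in seq_len(frame$nterm)) {
      b <- params$beta[[onames[k]]][[spec$terms[j]]]
      B[, j] <- if (length(b) == 1L) rep(b, C) else b
    }
    y <- frame$y[sel]
    X <- frame$X[sel, , drop = FALSE]
    up <- y < C
    if (any(up)) {
      cu <- y[up] + 1L
      eta_up[sel[up]] <- thr[cu] +
        if (frame$nterm) rowSums(X[up, , drop = FALSE] *
                                   B[cu, , drop = FALSE]) else 0
    }
    lo <- y > 0L
    if (any(lo)) {
      cl <- y[lo]
      eta_lo[sel[lo]] <- thr[cl] +
        if (frame$nterm) rowSums(X[lo, , drop = FALSE] *
                                   B[cl, , drop = FALSE]) else 0
    }
  }
  list(eta_up = eta_up, eta_lo = eta_lo)
}

# Chain rule from per-cell d loglik / d eta (A_up, A_lo) and the point-set
# gradient G_W back to the packed parameter vector. M is the standardized
# point matrix with W = M L'.
#' @keywords internal
frame_grad <- function(frame, params, A_up, A_lo, G_W, M) {
  spec <- frame$spec
  pidx <- frame$pidx
  onames <- vapply(spec$outcomes, `[[`, "", "name")
  g <- numeric(nrow(pidx))
  for (k in seq_len(spec$K)) {
    sel <- which(frame$k == k)
    nm <- onames[k]
    C <- frame$ncat[k] - 1L
    y <- if (length(sel)) frame$y[sel] else integer(0)
    au <- A_up[sel]; al <- A_lo[sel]
    # gradient w.r.t. the C thresholds: up contributes at cutpoint y,
    # lo at cutpoint y - 1 (0-based)
    g_thr <- numeric(C)
    if (length(sel)) {
      up <- y < C
      if (any(up)) {
        s <- rowsum(au[up], y[up])
        g_thr[as.integer(rownames(s)) + 1L] <-
          g_thr[as.integer(rownames(s)) + 1L] + s[, 1]
      }
      lo <- y > 0L
      if (any(lo)) {
        s <- rowsum(al[lo], y[lo] - 1L)
        g_thr[as.integer(rownames(s)) + 1L] <-
          g_thr[as.integer(rownames(s)) + 1L] + s[, 1]
      }
    }
    # chain through the increasing-threshold transform
    raw <- unconstrained_from_thresholds(params$thresholds[[nm]])
    tail_sums <- rev(cumsum(rev(g_thr)))
    g_raw <- c(tail_sums[1],
               if (C > 1L) exp(raw[-1]) * tail_sums[-1] else NULL)
    g[pidx$pos[pidx$type == "threshold_raw" & pidx$outcome == nm]] <- g_raw

    for (j in seq_len(frame$nterm)) {
      tm <- spec$terms[j]
      ppos <- pidx$pos[pidx$type == "coef" & pidx$outcome == nm &
                         pidx$term == tm]
      if (!length(sel)) next
      x <- frame$X[sel, j]
      if (length(ppos) == 1L) {
        g[ppos] <- sum((au + al) * x)
      } else {
        gt <- numeric(C)
        up <- y < C
        if (any(up)) {
          s <- rowsum(au[up] * x[up], y[up])
          gt[as.integer(rownames(s)) + 1L] <-
            gt[as.integer(rownames(s)) + 1L] + s[, 1]
        }
        lo <- y > 0L
        if (any(lo)) {
          s <- rowsum(al[lo] * x[lo], y[lo] - 1L)
          gt[as.integer(rownames(s)) + 1L] <-
            gt[as.integer(rownames(s)) + 1L] + s[, 1]
        }
        g[ppos] <- gt
      }
    }
  }
  if (spec$d > 0L && !is.null(G_W)) {
    G_L <- G_W %*% M  # d x d gradient w.r.t. the Cholesky factor
    cpos <- pidx[pidx$type == "chol", , drop = FALSE]
    gv <- numeric(nrow(cpos))
    for (i in seq_len(nrow(cpos))) {
      r <- cpos$row[i]; cc <- cpos$col[i]
      gv[i] <- if (r == cc) G_L[r, cc] * params$L[r, cc] else G_L[r, cc]
    }
    g[cpos$pos] <- gv
  }
  g
}

# Core evaluation: marginal log-likelihood (and optionally its gradient)
# for a packed parameter vector under a fixed rule. `std` caches the
# standardized point set for gh/qmc.
#' @keywords internal
loglik_core <- function(theta, frame, rule, std = NULL, want_grad = FALSE) {
  spec <- frame$spec
  params <- unpack_parameters(spec, theta)
  et <- frame_eta(frame, params)
  viol <- sum(is.finite(et$eta_up) & is.finite(et$eta_lo) &
                et$eta_up <= et$eta_lo)
  d <- spec$d

  if (rule$method == "agh" && d > 0L) {
    gq <- agh_grid(rule, d)
    res <- cpp_agh_loglik(et$eta_up, et$eta_lo, frame$t, frame$subj0,
                          frame$icol0, frame$scol0, params$Sigma,
                          gq$U, gq$loglam, frame$nsubj, 50L, 1e-8)
    if (want_grad) {
      stop("analytic gradients are only available for fixed-point rules; ",
           "use loglik_gradient(method = 'numeric') with 'agh'",
           call. = FALSE)
    }
    return(list(ll = res$ll, ll_subject = res$ll_subject,
                violations = viol, n_fallback = res$n_fallback))
  }

  if (d == 0L) {
    Wt <- matrix(0, 1, 1)
    logwt <- 0
    M <- NULL
  } else if (rule$method == "grid") {
    gp <- grid_points(rule, params$Sigma)
    Wt <- t(gp$W)
    logwt <- gp$logwt
    M <- NULL
    if (want_grad) stop("the dense-grid oracle has no analytic gradient",
                        call. = FALSE)
  } else {
    if (is.null(std)) std <- standardized_points(rule, d)
    M <- std$M
    Wt <- params$L %*% t(M)
    logwt <- std$logwt
  }

  res <- cpp_marginal_loglik(et$eta_up, et$eta_lo, frame$t, frame$subj0,
                             frame$icol0, frame$scol0, Wt, logwt,
                             frame$nsubj, isTRUE(want_grad))
  if (!is.finite(res$ll)) {
    bad <- which(!is.finite(res$ll_subject))[1]
    stop("integration failure: non-finite marginal likelihood for subject ",
         frame$subjects[bad], call. = FALSE)
  }
  out <- list(ll = res$ll, ll_subject = res$ll_subject, violations = viol)
  if (want_grad) {
    out$gradient <- frame_grad(frame, params, res$A_up, res$A_lo, res$G_W,
                               M)
  }
  out
}
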