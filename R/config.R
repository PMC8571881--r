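# Construction of specifications, truths and fit options from plain list
# structures (parsed YAML/JSON run configs); keeps the command-line
# front-end thin and testable.

#' Build a model specification from a config list
#'
#' Expected structure (YAML shown):
#' ```yaml
#' time: age
#' outcomes:
#'   - {name: Cig, n_categories: 5}
#' terms:
#'   age: per_cutpoint
#'   gender: shared
#'   "age:gender": per_cutpoint
#' random: {intercept: true, slope: true, correlation: full}
#' ```
#'
#' @param cfg Named list as parsed from YAML/JSON.
#' @return An [mvord_spec()].
#' @export
spec_from_config <- function(cfg) {
  if (is.null(cfg$outcomes)) stop("config field 'outcomes' is required",
                                  call. = FALSE)
  outs <- lapply(cfg$outcomes, function(o) {
    if (is.null(o$name) || is.null(o$n_categories)) {
      stop("each outcome needs fields 'name' and 'n_categories'",
           call. = FALSE)
    }
    outcome_def(o$name, o$n_categories, o$labels)
  })
  fixed <- unlist(cfg$terms %||% list())
  r <- cfg$random %||% list()
  random <- random_structure(
    intercept = r$intercept %||% TRUE,
    slope = r$slope %||% TRUE,
    correlation = r$correlation %||% "full"
  )
  mvord_spec(outs, fixed = fixed, random = random,
             time = cfg$time %||% "age")
}

#' Build a simulation truth from a config list
#'
#' The list holds a `spec` block (see [spec_from_config()]) plus
#' `thresholds` (named by outcome), `beta` (named by outcome, then term),
#' `sds`, `cor` (list of rows), and the design fields `n_subjects`,
#' `wave_months`, `p_male`, `baseline_bins`, `retention`, `p_missing`.
#'
#' @param cfg Named list as parsed from YAML/JSON.
#' @return An [truth_config()] object.
#' @export
truth_from_config <- function(cfg) {
  spec <- spec_from_config(cfg$spec %||% cfg)
  d <- spec$d
  cor <- cfg$cor %||% diag(d)
  if (is.list(cor)) cor <- do.call(rbind, lapply(cor, unlist))
  beta <- lapply(cfg$beta %||% list(), function(bk) lapply(bk, unlist))
  truth_config(
    spec = spec,
    thresholds = lapply(cfg$thresholds, unlist),
    beta = beta,
    sds = unlist(cfg$sds %||% numeric(d)),
    cor = cor,
    n_subjects = cfg$n_subjects %||% 300L,
    wave_months = unlist(cfg$wave_months %||% seq(0, 60, by = 12)),
    p_male = cfg$p_male %||% 0.5,
    baseline_bins = unlist(cfg$baseline_bins %||% 0L),
    bin_width = cfg$bin_width %||% 0.5,
    age_origin = cfg$age_origin %||% 13.5,
    retention = unlist(cfg$retention %||% 1),
    p_missing = cfg$p_missing %||% 0
  )
}

#' Build fit options from a config list
#'
#' Recognised fields: `loglik_tol`, `grad_tol`, `max_iter`, `se`, `seed`,
#' and an `integration` block with `method`, `nodes`, `points`, `seed`.
#'
#' @param cfg Named list; may be `NULL` for all defaults.
#' @param seed Overriding seed (e.g. from a `--seed` flag).
#' @return A [fit_options()] object.
#' @export
fit_options_from_config <- function(cfg = NULL, seed = NULL) {
  cfg <- cfg %||% list()
  s <- seed %||% cfg$seed %||% 1L
  integ <- NULL
  if (!is.null(cfg$integration)) {
    i <- cfg$integration
    integ <- integration_rule(
      method = i$method %||% "gh",
      nodes = i$nodes %||% 7L,
      points = i$points %||% 256L,
      seed = i$seed %||% s
    )
  }
  fit_options(
    loglik_tol = cfg$loglik_tol %||% 1e-8,
    grad_tol = cfg$grad_tol %||% 1e-4,
    max_iter = cfg$max_iter %||% 500L,
    integration = integ,
    seed = s,
    se = cfg$se %||% TRUE
  )
}
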