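---
title: "Joint mixed cumulative logit models for correlated longitudinal ordinal outcomes"
author: "mvordmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint mixed cumulative logit models for correlated longitudinal ordinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvordmix)
```

## The model

Longitudinal studies of substance use (and many other behavioural
phenomena) record several ordinal outcomes — say cigarette, alcohol and
marijuana use, each graded from "no use" (0) to "daily or near-daily use"
(C) — repeatedly on the same subjects. The scientific questions are about
*inter-outcome association*: is a subject's baseline level of one
substance associated with another's, and do age trends track each other?
Answering those questions requires a joint model, not K separate ones.

`mvordmix` fits the multivariate mixed cumulative logit model. For
outcome $k$, subject $i$, occasion $j$ and cutpoint $c = 0, \dots, C-1$:

$$
\operatorname{logit} \Pr(Y^k_{ij} \le c)
  = \beta^k_{0c} + \textstyle\sum_t x_{t,ij}\,\beta^k_{tc}
  + \nu^k_i + \mu^k_i t_{ij},
$$

with the stacked random intercepts and slopes
$W_i = (\nu^1_i, \mu^1_i, \dots, \nu^K_i, \mu^K_i) \sim N(0, \Sigma_w)$,
$\Sigma_w$ unstructured (dimension up to $2K$). Because the link is on
$\Pr(Y \le c)$, a **positive** coefficient shifts probability mass toward
*lower* categories; the sign convention is deliberately preserved from
the applied literature this model class comes from, and is asserted by a
monotonicity test in the suite.

Three fixed-effect regimes are supported per term and outcome:

* **proportional odds (PO)** — one coefficient shared by all C cumulative
  comparisons;
* **non-proportional odds (NPO)** — a separate coefficient per cutpoint;
* **partial proportional odds (PPO)** — any mixture of the two.

The PO model is the linear restriction of the NPO model in which the C
cutpoint copies coincide; `expand_po_to_npo()` implements the embedding
and the test suite verifies that the likelihood is invariant under it,
which is also what justifies the likelihood-ratio test of the PO
assumption (`lrt_proportional_odds()`, df = number of freed copies).
A Wald version (`wald_homogeneity()`) tests the same restriction through
the C − 1 consecutive-difference contrasts of a fitted NPO model. Both
tests are offered because no single canonical form exists for this
assumption in the mixed-model setting; they agree asymptotically, and the
suite checks they agree within 10% on a well-powered example.

## Parameterization

The optimizer works on a fully unconstrained vector:

* thresholds enter as a free first value plus log-increments, so any real
  vector maps to strictly increasing cutpoints. This ordering is enforced
  even for NPO models (at the covariate reference point); non-intercept
  per-cutpoint coefficients are *not* constrained, so fitted category
  probabilities can still cross away from the reference — exactly what
  the model class permits. Crossed cells encountered during optimization
  are floored at 1e-10, counted, and a fit that still has crossings at
  convergence is flagged `boundary_invalid` rather than silently
  accepted.
* $\Sigma_w$ enters through its lower-triangular Cholesky factor with
  log-transformed diagonal; any real vector maps to a valid (PSD)
  covariance. Under `correlation = "block_diagonal"` the cross-outcome
  entries of the factor are structurally zero and the joint likelihood
  factors exactly into the K univariate ones — the test suite exploits
  this as an internal consistency oracle.
* variance components are never constrained away from zero; a
  `variance_boundary` diagnostic flags |log-diagonal| > 10 instead
  (boundary maxima are legitimate).

`pack_parameters()` / `unpack_parameters()` form an exact bijection
(property-tested over random specifications).

## Integration of the random effects

The marginal likelihood integrates the conditional likelihood over
$W_i$. Four interchangeable rules are provided:

| rule | what it is | role |
|------|------------|------|
| `gh` | standardized Gauss–Hermite product rule, points scaled by the current Cholesky factor | default for d ≤ 3 (7 nodes/dim) |
| `qmc` | randomly shifted Halton sequence through the normal quantile map | default for d ≥ 4 (256 points) |
| `agh` | adaptive Gauss–Hermite, per-subject mode/curvature recentring (damped Newton, ≤ 50 steps, tol 1e-8, prior-centred fallback) | verification and high-accuracy evaluation |
| `grid` | trapezoid grid over ±8 SD, d ≤ 2 | brute-force oracle |

The fitting default is the *fixed-point* family (`gh`/`qmc`) rather than
the adaptive rule, a deliberate design choice: with the standardized
point set frozen for the whole fit, the approximate likelihood is a
smooth, exact function of the parameters, its gradient is available
analytically (chain rule through the threshold and Cholesky transforms),
line searches are coherent (common "random" numbers), and the optimum is
a true stationary point of one fixed function. The adaptive rule moves
its points with the parameters, which makes it the most accurate choice
per node for *evaluating* a likelihood — the suite requires AGH at 21
nodes to agree with the dense grid to 1e-6 — but a noisier target to
optimize; it remains available for fitting via finite-difference
gradients. A finite-difference gradient (`loglik_gradient(method =
"numeric")`, central differences, step `max(1e-5, 1e-5 |theta|)`) is kept
both as a fallback and as the cross-check that the analytic gradient must
match (tested to 1e-6).

QMC uses a generalized Halton sequence with a seed-derived random shift
(Cranley–Patterson rotation); the generator is a compact implementation
inside the package, keeping the dependency footprint small. The shift
seed is recorded in every fit for reproducibility.

Quadrature accuracy caveats: accuracy at a fixed node count degrades as
the random-slope SD times the time range grows — at realistic magnitudes
(intercept SD near 1, yearly slope SD near 0.1–0.3) AGH at 21 nodes
agrees with the brute-force grid to better than 1e-6, but a slope SD
above about 1 per year over several years produces integrands that need
substantially more nodes. Separately, the Cholesky factor is order-dependent, so
relabelling outcomes changes the scaled point set and the approximate
log-likelihood by the quadrature error (about 1e-3 at 5 nodes/dim in the
suite's example, an order less at 7). Model equivariance under relabeling
is therefore tested at that tolerance, not at machine precision.

## Estimation, standard errors, outputs

Fitting maximizes the marginal log-likelihood with PORT quasi-Newton
iterations (`nlminb`) on the unconstrained vector, followed, when the
gradient tolerance (default 1e-4 max-norm) is not yet met, by damped
Newton polishing steps using the central-difference Hessian of the
analytic gradient. That Hessian is the observed information; its inverse
is the covariance of the estimates, and standard errors for thresholds,
random-effect SDs and correlations follow by the delta method through
the respective transforms. Convergence is reported, never assumed; a
non-invertible information matrix flags SEs as undefined without
rejecting the fit. p-values are two-sided Wald tests without multiplicity
adjustment — per-coefficient inference is reported as is, and any
multiple-testing correction is the analyst's decision downstream.

The fitted $\Sigma_w$ is reported as SDs plus a labelled correlation
matrix (`re_correlation()`), ordered intercept-then-slope within outcome
(`CigInt`, `CigAge`, `AlcInt`, ... for the study preset), which is the
quantity of primary scientific interest: intercept–intercept entries are
baseline inter-outcome association, slope–slope entries association of
age trends, and negative intercept–slope entries the familiar
measurement-ceiling pattern (subjects starting high cannot rise much
further).

`predict_cumulative_curves()` produces, per outcome and covariate
setting, the curves $\Pr(Y \ge c+1)$ over time — from "any use" down to
"daily or near-daily use". The default conditions on $W_i = 0$ (the
median subject), because mixed-model coefficients are subject-specific;
a population-averaged variant integrates the logistic over the fitted
normal distribution of $\nu + \mu t$ (a one-dimensional integral
regardless of d, 41-node Gauss–Hermite) and is attenuated toward 0.5, a
property the suite asserts. Prediction outside the observed time range
errors unless explicitly allowed.

## Descriptive surface

`category_proportions()` and `observed_cumulative_logits()` reproduce
the model-free summaries that motivate the model: per group (e.g. gender
× half-year age band) category proportions and observed cumulative
logits. Empty cumulative cells yield ±Inf markers plus a
continuity-corrected column `log((cum + ½)/(n − cum + ½))` — reported
alongside, never substituted, so sparse cells stay visible. Age binning
is half-open `[low, high)` (an age on an edge belongs to the next bin)
and the relative-age time variable is `bin × width`, not a midpoint, so
intercepts refer to the first bin. The default geometry spans 13.5–26.5
years in half-year steps; the sources this design emulates describe that
range inconsistently (25 vs 26 bins), so the binning is parameterized
rather than hard-coded.

## The synthetic-data generator

Because the motivating cohort data are not public, the generator is a
first-class module: it draws gender (0 = female, 1 = male), a baseline
half-year age bin, correlated random effects, walks a wave schedule with
*monotone* dropout (once a wave is missed, all later waves are missed —
the simplest mechanism consistent with a reported mean observation count),
and draws each retained cell's category from the pmf implied by the
linear predictor. An NPO truth whose cumulative curves cross anywhere on
the realizable design support is rejected up front — the generator never
floors probabilities, that policy belongs to the estimator only.

`study_preset()` encodes the emulated design: K = 3 five-level outcomes,
N = 1263 subjects, waves at 0, 6, 15, 24, 48, 60, 72, 84 months, 56.6%
female, baseline age uniform over the first four half-year bins above
13.5 years (the enrollment-age distribution is not published; uniform
over the earliest bins keeps every wave inside the binning range), and a
constant per-wave retention of 0.9535, solved from
$(1-r^8)/(1-r) = 6.8$ so the expected observations per subject match the
reported mean. With that single tuned parameter the preset also gives
roughly 83% of subjects with 5+ observations (reported: 87%) — a
one-parameter dropout mechanism cannot match both summaries exactly, and
the mean was chosen as the primary target. The preset's coefficients and
$\Sigma_w$ are *illustrative round values* with the qualitative pattern
of the application (mild non-proportionality in age, steeper male
trends, positive baseline and trend correlations across outcomes,
negative intercept–slope correlations); they are not estimates from any
dataset, and nothing in the package treats them as such.

What passing simulation-based tests does and does not show: the
generator draws from exactly the model class the estimator fits, with
missingness at random and monotone dropout. Recovery and calibration
results therefore validate the estimator's correctness, not the model's
adequacy for any real cohort — real data bring informative dropout,
reporting heaping, cross-wave measure changes and covariate error that
this generator deliberately does not emulate.

## Problem sizes and numerical settings used in validation

The test suite runs, among others: a 50-replicate recovery study (two
correlated outcomes, 4 categories, N = 300, 6 occasions, random
intercept + slope per outcome, cross-outcome correlation 0.5; QMC with
256 points) checking mean absolute bias of fixed effects < 0.1,
random-effect SD bias < 0.15 and 95% Wald coverage in [0.88, 0.99]; and
a 200-replicate type-I-error study for the NPO-vs-PO LRT (K = 1,
N = 300, α = 0.05, acceptance band [0.01, 0.10]). The acceptance script
reruns the same computations at 20 and 100 replicates respectively —
sizes chosen so a complete from-scratch rerun stays a desk-scale job —
and reports the measured quantities rather than asserting them.

Numerical defaults: log-likelihood tolerance 1e-8, gradient max-norm
1e-4, at most 500 optimizer iterations, 7 GH nodes per dimension
(d ≤ 3) or 256 QMC points (d ≥ 4), starting values from
continuity-corrected empirical cumulative logits plus per-outcome
no-random-effects PO fits, Cholesky started at 0.5 I. All of these are
`fit_options()` arguments; every fit echoes its integration settings and
seed.

## Known limitations

* Logit link only (no probit or complementary log-log).
* Random structure is intercept and/or time slope per outcome; no
  higher-order random terms.
* Standard errors are observed-information Wald; no sandwich or profile
  intervals.
* Missingness is assumed at random given covariates and random effects;
  informative dropout is out of scope (and out of the generator).
* Empirical-Bayes subject-level predictions are not yet exposed.
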