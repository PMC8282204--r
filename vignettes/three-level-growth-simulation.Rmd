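---
title: "Monte Carlo evaluation of three-level growth models with growthmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo evaluation of three-level growth models with growthmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`growthmc` studies the sample-size behaviour of the three-level linear
growth model: repeated measures (level 1, occasions `t = 0, ..., T-1`)
nested in individuals (level 2) nested in groups (level 3), with one
standard-normal covariate at each of the two upper levels — `x` for
individuals, `z` for groups.  In combined form, for occasion `t` of
individual `i` in group `j`,

$$
y_{tij} = \underbrace{\gamma_{000} + \gamma_{001} z_j + u_{00j}
          + (\gamma_{010} + u_{01j})\,x_{ij} + r_{0ij}}_{\text{intercept}}
        + \big[\underbrace{\gamma_{100} + \gamma_{101} z_j + u_{10j}
          + (\gamma_{110} + u_{11j})\,x_{ij} + r_{1ij}}_{\text{slope}}\big]\,t
        + e_{tij},
$$

with mutually independent mean-zero normal random terms: the occasion
residual $e_{tij}\sim N(0,\sigma^2_e)$, individual-level intercept and
slope deviations $r_{0ij}, r_{1ij}$ with variances
$\sigma^2_{r0}, \sigma^2_{r1}$, and group-level deviations
$u_{00j}, u_{01j}, u_{10j}, u_{11j}$ with variances
$\sigma^2_{u00}, \sigma^2_{u01}, \sigma^2_{u10}, \sigma^2_{u11}$.  All
covariances between random terms are zero by default, in generation and in
estimation (a free-covariance option exists in both, off by default).

Time is coded `0, 1, 2, 3` so the intercept is initial status.  The
default fixed effects are 0.5 for the grand intercept and 0.3 — a medium
effect size — for every slope.

## ICC parameterization

Design cells are specified through the intercept-pathway intraclass
correlations $(\rho_1, \rho_2, \rho_3)$, the proportions of total
intercept-pathway variance $(\sigma^2_e + \sigma^2_{r0} + \sigma^2_{u00})$
at each level.  The two study sets are $(0.45, 0.50, 0.05)$ and
$(0.35, 0.50, 0.15)$.  An anchor pins the absolute scale: by default the
individual-level random-intercept variance $\sigma^2_{r0}$ is anchored at
2.0, so both sets share total 4.0 and resolve to the round components
$(1.8, 2.0, 0.2)$ and $(1.4, 2.0, 0.6)$.  A stated individual-level
residual variance of 2.0 is ambiguous in three-level terminology; we read
it as this level-2 anchor, and the alternative reading (occasion-level
$\sigma^2_e = 2.0$) is available via `anchor_level = 1`.  We prefer the
level-2 reading because it produces exact round components under both ICC
sets and intercept-pathway fixed-effect sampling variances of realistic
magnitude.

The level-3 ICC is defined conditionally on covariates: it uses
$\sigma^2_{u00}$, not the marginal group-level variance
$\sigma^2_{u00} + \gamma_{001}^2$.

### Slope-pathway variances

An intercept-pathway ICC triple says nothing about the slope-pathway
variances $\sigma^2_{r1}, \sigma^2_{u10}$ or the covariate-slope variances
$\sigma^2_{u01}, \sigma^2_{u11}$.  The source study does not state them.
The package's defaults are a single documented choice, made once:
$\sigma^2_{r1} = 0.5$ (slope variability a quarter of the intercept's),
$\sigma^2_{u10} = \sigma^2_{r1}\,\rho_3/\rho_2$ (the slope pathway reuses
the intercept pathway's level-3/level-2 ratio), and
$\sigma^2_{u01} = \sigma^2_{u11} = 0.1$.  All four are plainly
configurable (`icc_to_variances()` overrides, the `variances` field of a
configuration).  They are **not recoverable** from the summary statistics
such studies report — back-solving slope-row MSEs and powers gives
mutually inconsistent values — and this has a visible consequence
discussed under *Limitations*.

## The generator

`generate_dataset()` draws, per replication: group sizes independently
discrete-uniform on the design range (5–15 or 15–45, so the expected size
is the nominal 10 or 30; the total sample size is random), `z` per group
and `x` per individual from `N(0, 1)`, random effects from their normal
laws, and assembles `y` by the combined equation.  Every individual is
observed at all `T = 4` occasions; there is no missingness, no time-varying
covariate, and no non-normal residual option.  Passing tests therefore
speak to the estimator's behaviour under the generating model, not to
robustness against misspecification.  Reproducibility is strict: one
integer seed determines a dataset bit-for-bit, and per-replication seeds
are derived as `base_seed + r` with condition base seeds spaced
$10^6$ apart (mod $2^{31}-1$) from the master seed, so any single
replication can be regenerated in isolation and results are invariant to
parallel scheduling.

## The estimator

`fit_ml()` maximizes the profiled marginal likelihood.  Within group $j$
the marginal covariance is
$V_j = Z_{3j} G_3 Z_{3j}' + \mathrm{blockdiag}_i(Z_2 G_2 Z_2')
+ \sigma^2_e I$; the fixed effects are concentrated out by generalized
least squares, leaving a 7-parameter optimization (the 7 variances, plus
covariances when freed).  Implementation notes that matter numerically:

* **Factored evaluation.** Every individual shares the occasion design
  $Z_2 = [1\; t]$, so the individual-level block $W$ is a single
  $T \times T$ matrix per parameter value, and the group level is handled
  by the Woodbury identity and matrix determinant lemma.  All data enter
  through per-group sufficient statistics computed once per dataset, so one
  likelihood evaluation costs $O(J)$ small-matrix operations.  Feasibility
  (positive definiteness of $V_j$) is checked through the eigenvalues of
  $G_3^{1/2}$-type products and requires neither $G_2$ nor $G_3$ to be
  positive definite themselves.
* **Unconstrained variance scale.** The search runs on the variance scale,
  not log-variances, with infeasible points (non-positive-definite $V$)
  rejected by the line search.  This is deliberate: the study's convergence
  accounting counts fits with negative variance estimates as
  non-converged, an outcome a log parameterization could never produce.
* **Starting values** are moment-based: per-individual OLS lines give
  intercepts, slopes and the residual variance; within-group and
  between-group variance decompositions of those intercepts and slopes
  (noise-corrected, floored at $10^{-4}$) start the level-2 and level-3
  components; per-group regressions of intercept/slope on `x` start the
  covariate-slope variances.
* **Optimizer.** BFGS with a central-difference gradient, at most 500
  iterations, relative log-likelihood tolerance $10^{-8}$.  We use
  $10^{-8}$ rather than a looser $10^{-6}$ because the log-likelihood is in
  the thousands on study-sized data, and a relative $10^{-6}$ stop leaves
  enough slack at the optimum to perturb the numerical observed
  information.  Gradient steps are $10^{-4}(|\theta|+0.1)$ per component,
  Hessian steps $5\times 10^{-3}(|\theta|+0.1)$.
* **Inference.** Fixed-effect standard errors come from the GLS covariance
  at $\hat\theta$; variance-parameter standard errors from the inverse of
  the central-difference observed information of the *profile*
  log-likelihood (whose curvature already accounts for the estimated fixed
  effects).  All Wald tests use the standard normal reference and all 95%
  intervals are symmetric, estimate $\pm 1.96\,$SE, including for
  variances — mirroring mainstream ML software conventions rather than
  profile or log-scale intervals, because the study's outcome definitions
  are built on those conventions.
* **Classification.** `converged`: optimizer success and invertible
  information matrices; `inadmissible`: success with at least one negative
  variance estimate; `failed`: anything else.  Data-driven failures return
  a classified fit, never an error.

## Outcome statistics

Per design cell and parameter, over the **converged replications only**:
relative bias $(\bar{\hat\theta} - \theta)/\theta$ (undefined, and skipped,
for zero-valued truths such as the generating covariances), MSE
$\overline{(\hat\theta - \theta)^2}$ (identically squared bias plus
estimate variance), 95% coverage with closed interval endpoints, and power
as the proportion of two-sided p-values strictly below $\alpha = 0.05$
(ties at $\alpha$ do not reject).  The convergence rate is reported over
all attempted replications.  Conventional flags are attached where
absolute relative bias exceeds 5% or coverage leaves $[0.91, 0.98]$.

## Problem sizes used by the shipped checks

The test suite keeps every stochastic check at a size where its Monte
Carlo error is well inside the asserted tolerance: the dense-oracle
equivalence uses 20 datasets of 2–4 groups; the ICC-recovery checks use
balanced designs of 20,000–50,000 groups (the group-level component's
relative MC error must sit well under the 5% band); parameter recovery
uses 200 replications at 500 groups; the nominal-coverage and
printed-cell checks use the study's own 500 replications.  The acceptance
script runs the 30-group cells at the full 500 replications and the 50-
and 100-group cells at 200.

## Limitations

* **Convergence accounting vs. the original software.** Under the
  package's accounting — unconstrained ML, a fit with any negative
  variance estimate counted non-converged — the smallest cells (30 groups)
  converge in roughly 60–70% of replications with the default generating
  values, because the three small level-3 variances (0.05–0.1) each have
  estimator standard deviations of comparable size at $J = 30$.
  Comparable studies run with mainstream SEM software report 99.8–100%
  under nominally the same criterion.  No realistic slope-pathway variance
  configuration closes that gap: even values several times larger leave a
  nontrivial negative-estimate probability at $J = 30$.  The discrepancy
  therefore sits in such software's behaviour (its parameterization or
  convergence bookkeeping), not in a recoverable parameter value, and we
  kept the documented defaults rather than reverse-engineering them toward
  a reported convergence rate.
* **Selection effects.** Because summaries condition on convergence, cells
  with a material non-convergence fraction inherit a selection effect
  (e.g. replications with small group-level variance estimates are
  preferentially excluded, which nudges power for group-level effects
  downward relative to an unconditional accounting).  This is the study's
  own accounting rule, applied consistently.
* **Scope.** REML, robust standard errors, small-sample degrees-of-freedom
  corrections, Bayesian estimation, non-normal or missing outcomes, and
  more than three levels are out of scope.
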