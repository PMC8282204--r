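#' Fixed effects of the three-level growth model
#'
#' Bundles the six population regression coefficients of the linear growth
#' model with one individual-level covariate `x` and one group-level
#' covariate `z`.  The outcome at occasion `t` for individual `i` in group
#' `j` has conditional mean
#' \deqn{(\gamma_{000} + \gamma_{001} z_j + \gamma_{010} x_{ij}) +
#'       (\gamma_{100} + \gamma_{101} z_j + \gamma_{110} x_{ij})\, t.}
#'
#' Defaults are an intercept of 0.5 and a medium effect size of 0.3 for all
#' slopes.
#'
#' @param gamma_000 grand intercept (expected outcome at time 0 when
#'   `x = z = 0`).
#' @param gamma_001 effect of the group covariate `z` on the intercept.
#' @param gamma_010 effect of the individual covariate `x` on the intercept.
#' @param gamma_100 grand linear time slope.
#' @param gamma_101 effect of `z` on the time slope (cross-level
#'   interaction `t*z`).
#' @param gamma_110 effect of `x` on the time slope (`t*x`).
#' @return An object of class `gmc_fixed_effects`: a named numeric vector
#'   in the canonical order `gamma_000, gamma_001, gamma_010, gamma_100,
#'   gamma_101, gamma_110`.
#' @examples
#' fixed_effects()
#' fixed_effects(gamma_001 = 0)   # no group covariate effect
#' @export
fixed_effects <- function(gamma_000 = 0.5, gamma_001 = 0.3, gamma_010 = 0.3,
                          gamma_100 = 0.3, gamma_101 = 0.3, gamma_110 = 0.3) {
  fx <- c(gamma_000 = gamma_000, gamma_001 = gamma_001, gamma_010 = gamma_010,
          gamma_100 = gamma_100, gamma_101 = gamma_101, gamma_110 = gamma_110)
  if (!is.numeric(fx) || anyNA(fx) || any(!is.finite(fx)))
    stop("fixed effects must be finite numbers")
  structure(fx, class = "gmc_fixed_effects")
}

#' Variance components of the three-level growth model
#'
#' Variances of the mutually independent, mean-zero normal random terms at
#' the three levels: the occasion-level residual (`sigma2_e`), the
#' individual-level random intercept and time slope (`sigma2_r0`,
#' `sigma2_r1`), and the group-level random deviations of the intercept,
#' the `x`-on-intercept slope, the time slope, and the `x`-on-time slope
#' (`sigma2_u00`, `sigma2_u01`, `sigma2_u10`, `sigma2_u11`).
#'
#' All covariances between random terms are zero by default; `sigma_r01`
#' (individual-level intercept-slope covariance) and `sigma_u_offdiag`
#' (applied to every group-level pair) allow correlated effects in
#' generation.
#'
#' @param sigma2_e occasion-level residual variance.
#' @param sigma2_r0,sigma2_r1 individual-level intercept and slope variances.
#' @param sigma2_u00,sigma2_u01,sigma2_u10,sigma2_u11 group-level variances.
#' @param sigma_r01 individual-level intercept-slope covariance (default 0).
#' @param sigma_u_offdiag common covariance for all group-level pairs
#'   (default 0).
#' @return An object of class `gmc_varcomp` (named numeric vector).
#' @examples
#' variance_components(sigma2_e = 1.8, sigma2_u00 = 0.2)
#' @export
variance_components <- function(sigma2_e = 1.8, sigma2_r0 = 2.0,
                                sigma2_r1 = 0.5, sigma2_u00 = 0.2,
                                sigma2_u01 = 0.1, sigma2_u10 = 0.05,
                                sigma2_u11 = 0.1, sigma_r01 = 0,
                                sigma_u_offdiag = 0) {
  vc <- c(sigma2_e = sigma2_e, sigma2_r0 = sigma2_r0, sigma2_r1 = sigma2_r1,
          sigma2_u00 = sigma2_u00, sigma2_u01 = sigma2_u01,
          sigma2_u10 = sigma2_u10, sigma2_u11 = sigma2_u11,
          sigma_r01 = sigma_r01, sigma_u_offdiag = sigma_u_offdiag)
  if (anyNA(vc) || any(!is.finite(vc)))
    stop("variance components must be finite numbers")
  if (any(vc[1:7] < 0))
    stop("variances must be >= 0 for data generation")
  structure(vc, class = "gmc_varcomp")
}

#' Intraclass correlation specification
#'
#' Describes how the total intercept-pathway variance is partitioned across
#' the three levels, plus the anchor that pins the absolute scale.  By
#' default the individual-level (level-2) random-intercept variance is
#' anchored at 2.0, so the common total is
#' `anchor_variance / icc_level2` and each component is its ICC share of
#' that total.  Setting `anchor_level = 1` instead anchors the
#' occasion-level residual variance at `anchor_variance`.
#'
#' @param icc_level1,icc_level2,icc_level3 proportions of intercept-pathway
#'   variance at each level; must be in (0, 1) and sum to 1.
#' @param anchor_variance the variance pinned to the anchored level
#'   (default 2.0).
#' @param anchor_level which level the anchor refers to: 2 (individual-level
#'   random intercept, the default) or 1 (occasion residual).
#' @return An object of class `gmc_icc`.
#' @examples
#' icc_spec(0.45, 0.50, 0.05)
#' icc_spec(0.35, 0.50, 0.15)
#' @export
icc_spec <- function(icc_level1, icc_level2, icc_level3,
                     anchor_variance = 2.0, anchor_level = 2L) {
  p <- c(icc_level1, icc_level2, icc_level3)
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("each ICC proportion must lie strictly in (0, 1)")
  if (abs(sum(p) - 1) > 1e-12)
    stop("ICC proportions must sum to 1 (got ", format(sum(p)), ")")
  if (!anchor_level %in% c(1L, 2L))
    stop("anchor_level must be 1 or 2")
  if (anchor_variance <= 0) stop("anchor_variance must be > 0")
  structure(list(icc_level1 = p[1], icc_level2 = p[2], icc_level3 = p[3],
                 anchor_variance = anchor_variance,
                 anchor_level = as.integer(anchor_level)),
            class = "gmc_icc")
}

#' Convert an ICC specification into intercept-pathway variances
#'
#' Solves the proportion equations for the three intercept-pathway variance
#' components.  With the default level-2 anchor, `sigma2_r0 =
#' anchor_variance`, the common total is `anchor_variance / icc_level2`,
#' and `sigma2_e` and `sigma2_u00` are their ICC shares of the total.
#' Slope-pathway variances are left at the `variance_components()` defaults:
#' they are not identified by an intercept-pathway ICC triple.
#'
#' @param spec a [icc_spec()] object.
#' @param ... overrides passed on to [variance_components()] for the fields
#'   the ICC does not determine (e.g. `sigma2_r1`).
#' @return A `gmc_varcomp` with `sigma2_e`, `sigma2_r0`, `sigma2_u00` set
#'   from the ICC and `sigma2_u10` scaled as `sigma2_r1 *
#'   icc_level3 / icc_level2` (same level-3/level-2 ratio as the intercept
#'   pathway) unless overridden.
#' @examples
#' icc_to_variances(icc_spec(0.45, 0.50, 0.05))  # 1.8 / 2.0 / 0.2
#' icc_to_variances(icc_spec(0.35, 0.50, 0.15))  # 1.4 / 2.0 / 0.6
#' @export
icc_to_variances <- function(spec, ...) {
  stopifnot(inherits(spec, "gmc_icc"))
  total <- if (spec$anchor_level == 2L) spec$anchor_variance / spec$icc_level2
           else                         spec$anchor_variance / spec$icc_level1
  dots <- list(...)
  args <- list(sigma2_e   = spec$icc_level1 * total,
               sigma2_r0  = spec$icc_level2 * total,
               sigma2_u00 = spec$icc_level3 * total)
  sigma2_r1 <- if (!is.null(dots$sigma2_r1)) dots$sigma2_r1 else 0.5
  if (is.null(dots$sigma2_u10))
    args$sigma2_u10 <- sigma2_r1 * spec$icc_level3 / spec$icc_level2
  args[names(dots)] <- dots
  do.call(variance_components, args)
}

#' Intercept-pathway ICCs implied by variance components
#'
#' The inverse of [icc_to_variances()]: each intercept-pathway variance
#' divided by their sum, returned as `(icc1, icc2, icc3)`.
#'
#' @param vc a `gmc_varcomp` object (or named vector with `sigma2_e`,
#'   `sigma2_r0`, `sigma2_u00`).
#' @return Named numeric vector `c(icc_level1, icc_level2, icc_level3)`.
#' @examples
#' theoretical_icc(variance_components(sigma2_e = 1.8, sigma2_u00 = 0.2))
#' @export
theoretical_icc <- function(vc) {
  v <- unclass(vc)[c("sigma2_e", "sigma2_r0", "sigma2_u00")]
  if (anyNA(v)) stop("vc must carry sigma2_e, sigma2_r0 and sigma2_u00")
  tot <- sum(v)
  if (tot <= 0) stop("intercept-pathway variances are all zero")
  stats::setNames(as.numeric(v / tot),
                  c("icc_level1", "icc_level2", "icc_level3"))
}

#' One cell of the simulation design
#'
#' @param n_groups number of level-3 groups.
#' @param group_size_range inclusive integer interval for the number of
#'   individuals per group, e.g. `c(5, 15)`.
#' @param icc a [icc_spec()] giving the variance partition for the cell.
#' @param n_timepoints number of equally spaced occasions per individual,
#'   coded `0 .. n_timepoints - 1`; at least 3 are required to identify a
#'   linear change model.
#' @param n_replications Monte Carlo replications for the cell.
#' @param base_seed integer seed from which per-replication seeds are
#'   derived (`replication_seed(base_seed, r)`).
#' @param label optional condition label.
#' @return Object of class `gmc_condition`.
#' @examples
#' design_condition(30, c(5, 15), icc_spec(0.45, 0.5, 0.05), base_seed = 7)
#' @export
design_condition <- function(n_groups, group_size_range, icc,
                             n_timepoints = 4L, n_replications = 500L,
                             base_seed = 1L, label = NULL) {
  stopifnot(inherits(icc, "gmc_icc"))
  n_groups <- as.integer(n_groups)
  rng <- as.integer(group_size_range)
  if (length(rng) != 2L || rng[1] < 1L || rng[1] > rng[2])
    stop("group_size_range must be c(min, max) with 1 <= min <= max")
  if (n_groups < 2L) stop("need at least 2 groups")
  if (n_timepoints < 3L)
    stop("at least three occasions are required for a linear growth model")
  if (is.null(label))
    label <- sprintf("icc3_%s_J%d_n%d", format(icc$icc_level3), n_groups,
                     round(mean(rng)))
  structure(list(n_groups = n_groups, group_size_range = rng,
                 icc = icc, n_timepoints = as.integer(n_timepoints),
                 n_replications = as.integer(n_replications),
                 base_seed = as.integer(base_seed), label = label),
            class = "gmc_condition")
}

#' @export
print.gmc_condition <- function(x, ...) {
  cat(sprintf(
    "three-level growth design cell '%s'\n  groups: %d, group size: %d-%d, occasions: %d\n  ICC (l1/l2/l3): %.2f/%.2f/%.2f, replications: %d, base seed: %d\n",
    x$label, x$n_groups, x$group_size_range[1], x$group_size_range[2],
    x$n_timepoints, x$icc$icc_level1, x$icc$icc_level2, x$icc$icc_level3,
    x$n_replications, x$base_seed))
  invisible(x)
}

## Seed derivation: independent, reproducible integer streams below 2^31.
## Condition base seeds are spaced 10^6 apart (mod 2^31 - 1) so that the
## per-replication seeds base + r never collide across cells of one grid.
.seed_mod <- 2147483647

#' Derive the base seed for a grid cell
#' @param master_seed master integer seed of the whole grid.
#' @param condition_index 1-based index of the cell in the grid ordering.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
condition_seed <- function(master_seed, condition_index) {
  as.integer((as.numeric(master_seed) * 1000003 +
              as.numeric(condition_index) * 1e6) %% .seed_mod)
}

#' Derive the seed for one replication
#' @param base_seed the condition's base seed.
#' @param replication 1-based replication index.
#' @return integer seed.
#' @export
replication_seed <- function(base_seed, replication) {
  as.integer((as.numeric(base_seed) + as.numeric(replication)) %% .seed_mod)
}

#' The full 2 x 3 x 2 condition grid
#'
#' Cartesian product of the two ICC sets (level-3 ICC 0.05 or 0.15), the
#' three group counts (30, 50, 100) and the two group-size ranges
#' (5-15, nominal size 10; 15-45, nominal size 30), in that nesting order
#' (ICC slowest, group-size range fastest).  Each cell gets a distinct base
#' seed derived from `master_seed`.
#'
#' @param master_seed integer master seed.
#' @param n_replications replications per cell (default 500).
#' @param n_timepoints occasions per individual (default 4).
#' @param anchor_variance,anchor_level passed to [icc_spec()].
#' @return List of 12 `gmc_condition` objects.
#' @examples
#' length(build_condition_grid(1))
#' @export
build_condition_grid <- function(master_seed = 1L, n_replications = 500L,
                                 n_timepoints = 4L, anchor_variance = 2.0,
                                 anchor_level = 2L) {
  icc_sets <- list(icc_spec(0.45, 0.50, 0.05, anchor_variance, anchor_level),
                   icc_spec(0.35, 0.50, 0.15, anchor_variance, anchor_level))
  group_counts <- c(30L, 50L, 100L)
  size_ranges <- list(c(5L, 15L), c(15L, 45L))
  grid <- list()
  k <- 0L
  for (icc in icc_sets)
    for (J in group_counts)
      for (rng in size_ranges) {
        k <- k + 1L
        grid[[k]] <- design_condition(
          J, rng, icc, n_timepoints = n_timepoints,
          n_replications = n_replications,
          base_seed = condition_seed(master_seed, k))
      }
  grid
}

#' Bundle generating parameters
#'
#' @param fixed a [fixed_effects()] object.
#' @param varcomp a [variance_components()] object.
#' @return Object of class `gmc_params` with elements `fixed` and `varcomp`.
#' @export
generation_params <- function(fixed = fixed_effects(),
                              varcomp = variance_components()) {
  stopifnot(inherits(fixed, "gmc_fixed_effects"),
            inherits(varcomp, "gmc_varcomp"))
  structure(list(fixed = fixed, varcomp = varcomp), class = "gmc_params")
}

#' Generating parameters for a design cell
#'
#' Applies [icc_to_variances()] to the cell's ICC specification and merges
#' any explicit overrides.
#'
#' @param condition a `gmc_condition`.
#' @param fixed fixed effects (default [fixed_effects()]).
#' @param ... variance overrides forwarded to [icc_to_variances()].
#' @return A `gmc_params` object.
#' @export
params_for_condition <- function(condition, fixed = fixed_effects(), ...) {
  stopifnot(inherits(condition, "gmc_condition"))
  generation_params(fixed, icc_to_variances(condition$icc, ...))
}

#' Truth vector in estimator parameter order
#'
#' @param params a `gmc_params` object.
#' @return Named numeric vector over the 6 fixed effects followed by the 7
#'   variance components, the order reported by [fit_ml()].
#' @export
true_values <- function(params) {
  stopifnot(inherits(params, "gmc_params"))
  c(unclass(params$fixed),
    unclass(params$varcomp)[c("sigma2_e", "sigma2_r0", "sigma2_r1",
                              "sigma2_u00", "sigma2_u01", "sigma2_u10",
                              "sigma2_u11")])
}
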