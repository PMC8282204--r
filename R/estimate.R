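## Canonical parameter orders.  Fixed design columns: 1, z, x, t, t*z, t*x.
.fx_names <- c("gamma_000", "gamma_001", "gamma_010",
               "gamma_100", "gamma_101", "gamma_110")
.vc_diag_names <- c("sigma2_e", "sigma2_r0", "sigma2_r1",
                    "sigma2_u00", "sigma2_u01", "sigma2_u10", "sigma2_u11")
.l2_cov_name <- "sigma_r01"
.l3_cov_names <- c("sigma_u00_u01", "sigma_u00_u10", "sigma_u00_u11",
                   "sigma_u01_u10", "sigma_u01_u11", "sigma_u10_u11")

.theta_names <- function(free_l2, free_l3) {
  nm <- c("sigma2_e", "sigma2_r0", "sigma2_r1")
  if (free_l2) nm <- c(nm, .l2_cov_name)
  nm <- c(nm, "sigma2_u00", "sigma2_u01", "sigma2_u10", "sigma2_u11")
  if (free_l3) nm <- c(nm, .l3_cov_names)
  nm
}

## Sort into (group, individual, time) order and build the design matrices.
.model_matrices <- function(data) {
  d <- as.data.frame(data)
  d <- d[order(d$group_id, d$individual_id, d$time), , drop = FALSE]
  tt <- d$time
  X <- cbind(1, d$z, d$x, tt, tt * d$z, tt * d$x)
  colnames(X) <- .fx_names
  Z3 <- cbind(1, d$x, tt, tt * d$x)
  ind <- interaction(d$group_id, d$individual_id, drop = TRUE)
  T_ <- as.integer(max(tt)) + 1L
  ni <- as.integer(tapply(d$individual_id, d$group_id,
                          function(v) length(unique(v))))
  list(d = d, X = X, y = d$y, Z3 = Z3, ni = ni, T = T_,
       n_ind = nlevels(ind))
}

#' Estimation settings for [fit_ml()]
#'
#' @param reltol relative tolerance on the log-likelihood change used by the
#'   quasi-Newton optimizer.
#' @param maxit maximum optimizer iterations.
#' @param grad_h,hess_h step-size scale factors for the central-difference
#'   gradient and observed-information Hessian; actual steps are
#'   `scale * (|theta| + 0.1)` per component.
#' @param start_floor lower floor applied to moment-based starting variances.
#' @param free_l2_cov,free_l3_cov estimate the intercept-slope covariances
#'   at level 2 / all covariances at level 3 instead of fixing them at zero
#'   (off by default, matching the zero-covariance generating model).
#' @param se compute standard errors (observed information for the variance
#'   parameters); disable for speed when only point estimates are needed.
#' @return A list of class `gmc_control`.
#' @export
fit_control <- function(reltol = 1e-8, maxit = 500L, grad_h = 1e-4,
                        hess_h = 5e-3, start_floor = 1e-4,
                        free_l2_cov = FALSE, free_l3_cov = FALSE, se = TRUE) {
  structure(list(reltol = reltol, maxit = as.integer(maxit), grad_h = grad_h,
                 hess_h = hess_h, start_floor = start_floor,
                 free_l2_cov = isTRUE(free_l2_cov),
                 free_l3_cov = isTRUE(free_l3_cov), se = isTRUE(se)),
            class = "gmc_control")
}

#' Marginal covariance matrix of one group
#'
#' Assembles `V_j = Z3 G3 Z3' + blockdiag_i(Z2 G2 Z2') + sigma2_e I` for
#' the observations of a single group, in (individual, time) order.  Mainly
#' a building block for tests and illustration; [fit_ml()] uses a factored
#' form internally.
#'
#' @param theta named vector with the seven variance components (names as
#'   in [variance_components()]); `sigma_r01` and the `sigma_u00_u01` ...
#'   pairwise level-3 covariances are honoured when present.
#' @param group_data rows of a long dataset belonging to one group.
#' @return The symmetric covariance matrix (`n_obs` x `n_obs`).
#' @export
build_group_covariance <- function(theta, group_data) {
  th <- unclass(theta)
  if (length(unique(group_data$group_id)) != 1L)
    stop("group_data must contain exactly one group")
  d <- group_data[order(group_data$individual_id, group_data$time), ,
                  drop = FALSE]
  n <- nrow(d)
  g2 <- matrix(c(th[["sigma2_r0"]],
                 if (!is.na(th["sigma_r01"])) th[["sigma_r01"]] else 0,
                 if (!is.na(th["sigma_r01"])) th[["sigma_r01"]] else 0,
                 th[["sigma2_r1"]]), 2, 2)
  g3 <- diag(th[c("sigma2_u00", "sigma2_u01", "sigma2_u10", "sigma2_u11")])
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(nrow(pairs))) {
    nm <- .l3_cov_names[k]
    v <- if (!is.na(th[nm])) th[[nm]] else if (!is.na(th["sigma_u_offdiag"]))
      th[["sigma_u_offdiag"]] else 0
    g3[pairs[k, 1], pairs[k, 2]] <- g3[pairs[k, 2], pairs[k, 1]] <- v
  }
  z2 <- cbind(1, d$time)
  z3 <- cbind(1, d$x, d$time, d$time * d$x)
  same_ind <- outer(d$individual_id, d$individual_id, "==")
  V <- z3 %*% g3 %*% t(z3) + (z2 %*% g2 %*% t(z2)) * same_ind +
    diag(th[["sigma2_e"]], n)
  0.5 * (V + t(V))
}

#' Profiled log-likelihood of the variance parameters
#'
#' Concentrates the fixed effects out by generalized least squares:
#' `beta(theta) = (sum_j X_j' V_j^-1 X_j)^-1 sum_j X_j' V_j^-1 y_j`, then
#' evaluates the marginal normal log-likelihood
#' `-0.5 * sum_j (log|V_j| + r_j' V_j^-1 r_j + n_j log 2 pi)`.
#'
#' @param theta variance-parameter vector in the order given by
#'   [fit_ml()]'s variance block: `sigma2_e, sigma2_r0, sigma2_r1`
#'   (`sigma_r01` if `free_l2_cov`), `sigma2_u00 .. sigma2_u11`
#'   (pairwise covariances if `free_l3_cov`).
#' @param data a long dataset.
#' @param free_l2_cov,free_l3_cov covariance structure flags.
#' @return List with `loglik` (NA if `V` is not positive definite at
#'   `theta`), `beta` (GLS fixed effects) and `cov_beta`.
#' @export
profile_loglik <- function(theta, data, free_l2_cov = FALSE,
                           free_l3_cov = FALSE) {
  mm <- .model_matrices(data)
  ptr <- .gmc_make_suffstats(mm$X, mm$y, mm$Z3, mm$ni, mm$T)
  r <- .gmc_ll_full(ptr, as.numeric(theta), free_l2_cov, free_l3_cov)
  if (r$status != 0)
    return(list(loglik = NA_real_, beta = NULL, cov_beta = NULL,
                status = r$status))
  list(loglik = r$loglik,
       beta = stats::setNames(as.numeric(r$beta), .fx_names),
       cov_beta = r$cov_beta, status = 0L)
}

## Moment-based starting values: per-individual OLS lines, then a variance
## decomposition of their intercepts and slopes within and between groups.
.start_values <- function(mm, control) {
  T_ <- mm$T
  tt <- seq.int(0, T_ - 1)
  tbar <- mean(tt)
  Stt <- sum((tt - tbar)^2)
  Y <- matrix(mm$y, nrow = T_)                  # occasions x individuals
  b <- colSums((tt - tbar) * Y) / Stt
  a <- colMeans(Y) - b * tbar
  fit <- outer(tt, rep(1, ncol(Y))) * rep(b, each = T_) + rep(a, each = T_)
  s2e <- sum((Y - fit)^2) / (ncol(Y) * (T_ - 2))
  lev_a <- s2e * (1 / T_ + tbar^2 / Stt)        # OLS noise in the intercepts
  lev_b <- s2e / Stt

  gi <- rep.int(seq_along(mm$ni), mm$ni)
  within_var <- function(v) {
    ssq <- sum(tapply(v, gi, function(u) sum((u - mean(u))^2)))
    ssq / max(length(v) - length(mm$ni), 1)
  }
  va_w <- within_var(a); vb_w <- within_var(b)
  abar <- tapply(a, gi, mean); bbar <- tapply(b, gi, mean)
  nbar <- mean(mm$ni)
  fl <- control$start_floor
  st <- c(max(s2e, fl),
          max(va_w - lev_a, fl),
          max(vb_w - lev_b, fl))
  if (control$free_l2_cov) st <- c(st, 0)
  # group-level covariate slopes: per-group OLS of a (and b) on x
  x_i <- mm$d$x[mm$d$time == 0]
  cov_slope_var <- function(v) {
    cf <- mapply(function(vg, xg) {
      sxx <- sum((xg - mean(xg))^2)
      if (length(vg) < 3 || sxx < 1e-8) return(c(NA, NA))
      c(sum((xg - mean(xg)) * vg) / sxx, 1 / sxx)
    }, split(v, gi), split(x_i, gi))
    if (all(is.na(cf[1, ]))) return(0.05)
    noise <- within_var(v) * mean(cf[2, ], na.rm = TRUE)
    max(stats::var(cf[1, ], na.rm = TRUE) - noise, fl)
  }
  st <- c(st,
          max(stats::var(abar) - va_w / nbar, fl),
          cov_slope_var(a),
          max(stats::var(bbar) - vb_w / nbar, fl),
          cov_slope_var(b))
  if (control$free_l3_cov) st <- c(st, rep(0, 6))
  st
}

#' Fit the three-level growth model by maximum likelihood
#'
#' Maximizes the profiled marginal likelihood over the variance parameters
#' (unconstrained variance scale, so negative variance estimates can and do
#' occur; points where the implied covariance matrix is not positive
#' definite are treated as infeasible) with a BFGS quasi-Newton search from
#' moment-based starting values.  Fixed-effect standard errors come from
#' the GLS covariance at the optimum; variance-parameter standard errors
#' from the inverse observed information (central-difference Hessian of the
#' profile log-likelihood).  All parameters get Wald z statistics, two-sided
#' p-values, and symmetric 95% confidence intervals `estimate +/- 1.96 SE`.
#'
#' A fit is flagged `converged` when the optimizer reported success and the
#' information matrices (GLS and observed) are invertible, and `admissible`
#' when every variance estimate is non-negative; data-driven failures are
#' returned as non-converged fits, never as errors.
#'
#' @param data a long dataset (see [generate_dataset()] /
#'   [read_long_csv()]); at least 2 groups.
#' @param control a [fit_control()] object.
#' @return An object of class `gmc_fit`: list with `estimates`, `se`, `z`,
#'   `p_value`, `ci_lower`, `ci_upper` (named over the 6 fixed effects and
#'   the variance parameters), `loglik`, `converged`, `admissible`,
#'   `classification`, `optim_status`, `n_obs`, `n_groups`, `message`.
#' @examples
#' cond <- design_condition(30, c(5, 15), icc_spec(0.45, 0.5, 0.05))
#' d <- generate_dataset(params_for_condition(cond), cond, seed = 1)
#' fit <- fit_ml(d)
#' fit$estimates[["gamma_001"]]
#' @export
fit_ml <- function(data, control = fit_control()) {
  stopifnot(inherits(control, "gmc_control"))
  nm <- c(.fx_names, .theta_names(control$free_l2_cov, control$free_l3_cov))
  fail <- function(msg, n_obs = NA_integer_, n_groups = NA_integer_) {
    k <- length(nm)
    v <- stats::setNames(rep(NA_real_, k), nm)
    structure(list(estimates = v, se = v, z = v, p_value = v,
                   ci_lower = v, ci_upper = v, loglik = NA_real_,
                   converged = FALSE, admissible = FALSE,
                   classification = "failed", optim_status = NA_integer_,
                   n_obs = n_obs, n_groups = n_groups, message = msg,
                   control = control), class = "gmc_fit")
  }

  v <- tryCatch(validate_dataset(data), error = function(e) e)
  if (inherits(v, "error")) return(fail(conditionMessage(v)))
  mm <- .model_matrices(data)
  if (length(mm$ni) < 2L) return(fail("need at least 2 groups",
                                      nrow(mm$d), length(mm$ni)))
  if (stats::sd(mm$y) == 0) return(fail("outcome is constant",
                                        nrow(mm$d), length(mm$ni)))

  ptr <- .gmc_make_suffstats(mm$X, mm$y, mm$Z3, mm$ni, mm$T)
  f2 <- control$free_l2_cov; f3 <- control$free_l3_cov
  start <- .start_values(mm, control)
  hstep <- function(th, sc) sc * (abs(th) + 0.1)

  fn <- function(th) {
    val <- .gmc_ll(ptr, th, f2, f3)
    if (is.na(val)) 1e10 else -val
  }
  gr <- function(th) -.gmc_grad(ptr, th, f2, f3, hstep(th, control$grad_h))

  opt <- tryCatch(
    stats::optim(start, fn, gr, method = "BFGS",
                 control = list(maxit = control$maxit,
                                reltol = control$reltol)),
    error = function(e) e)
  if (inherits(opt, "error"))
    return(fail(conditionMessage(opt), nrow(mm$d), length(mm$ni)))

  theta_hat <- opt$par
  full <- .gmc_ll_full(ptr, theta_hat, f2, f3)
  if (full$status != 0 || !is.finite(full$loglik))
    return(fail("likelihood not evaluable at the optimum",
                nrow(mm$d), length(mm$ni)))

  est <- stats::setNames(c(as.numeric(full$beta), theta_hat), nm)
  se <- stats::setNames(rep(NA_real_, length(nm)), nm)
  se[.fx_names] <- sqrt(pmax(diag(full$cov_beta), 0))
  info_ok <- all(is.finite(se[.fx_names])) && all(se[.fx_names] > 0)

  if (control$se) {
    H <- .gmc_hess(ptr, theta_hat, f2, f3, hstep(theta_hat, control$hess_h))
    cov_theta <- try(solve(-H), silent = TRUE)
    if (inherits(cov_theta, "try-error") || anyNA(cov_theta) ||
        any(diag(cov_theta) <= 0)) {
      info_ok <- FALSE
    } else {
      se[-seq_len(6)] <- sqrt(diag(cov_theta))
    }
  }

  zq <- stats::qnorm(0.975)
  zstat <- est / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  var_names <- intersect(.vc_diag_names, nm)
  admissible <- all(est[var_names] >= 0)
  converged <- (opt$convergence == 0L) && info_ok
  classification <- if (converged && admissible) "converged"
    else if (converged) "inadmissible" else "failed"

  structure(list(estimates = est, se = se, z = zstat, p_value = pval,
                 ci_lower = est - zq * se, ci_upper = est + zq * se,
                 loglik = full$loglik, converged = converged,
                 admissible = admissible, classification = classification,
                 optim_status = opt$convergence, n_obs = nrow(mm$d),
                 n_groups = length(mm$ni),
                 message = if (opt$convergence == 0L) "ok"
                           else "optimizer did not converge",
                 control = control),
            class = "gmc_fit")
}

#' Convergence/admissibility classification of a fit
#'
#' A replication counts as properly converged only when the optimizer
#' succeeded, the information matrix is non-singular, and no variance
#' estimate is negative; a successful optimum with a negative variance is
#' `"inadmissible"`, anything else `"failed"`.  Only `"converged"`
#' replications enter the Monte Carlo summaries.
#'
#' @param fit a `gmc_fit`.
#' @return One of `"converged"`, `"inadmissible"`, `"failed"`.
#' @export
classify_convergence <- function(fit) {
  stopifnot(inherits(fit, "gmc_fit"))
  fit$classification
}

#' @export
print.gmc_fit <- function(x, ...) {
  cat(sprintf("three-level growth model ML fit (%s)\n", x$classification))
  cat(sprintf("  observations: %s, groups: %s, logLik: %s\n",
              x$n_obs, x$n_groups,
              if (is.finite(x$loglik)) sprintf("%.3f", x$loglik) else "NA"))
  print(round(data.frame(estimate = x$estimates, se = x$se,
                         p = x$p_value), 4))
  invisible(x)
}

#' Flat per-parameter record of a fit
#'
#' @param x a `gmc_fit`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return Data frame with one row per parameter: `parameter`, `estimate`,
#'   `se`, `z`, `p_value`, `ci_lower`, `ci_upper`, plus the fit-level
#'   `classification` repeated.
#' @export
as.data.frame.gmc_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(parameter = names(x$estimates), estimate = unname(x$estimates),
             se = unname(x$se), z = unname(x$z),
             p_value = unname(x$p_value), ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper),
             classification = x$classification, row.names = NULL)
}

#' Write a fit as a flat JSON record
#'
#' @param fit a `gmc_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  rec <- list(parameters = as.data.frame(fit), loglik = fit$loglik,
              converged = fit$converged, admissible = fit$admissible,
              classification = fit$classification,
              n_obs = fit$n_obs, n_groups = fit$n_groups)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
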