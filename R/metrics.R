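#' Monte Carlo outcome statistics
#'
#' The five statistics used to judge each design cell: convergence rate,
#' relative parameter bias, mean squared error, 95% confidence-interval
#' coverage, and power.
#'
#' @param estimates numeric vector of per-replication estimates (converged
#'   replications only).
#' @param truth the generating value.
#' @name mc_statistics
NULL

#' @describeIn mc_statistics `(mean(estimates) - truth) / truth`; undefined
#'   (error) when `truth == 0`, which is why zero-valued generating
#'   covariances never appear in bias tables.
#' @export
relative_bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop("no estimates supplied")
  if (truth == 0) stop("relative bias is undefined for a zero true value")
  (mean(estimates) - truth) / truth
}

#' @describeIn mc_statistics mean of `(estimate - truth)^2`, identically the
#'   squared bias plus the population variance of the estimates.
#' @export
mse <- function(estimates, truth) {
  if (length(estimates) < 2) stop("need at least 2 estimates for an MSE")
  mean((estimates - truth)^2)
}

#' @describeIn mc_statistics proportion of intervals whose closed range
#'   `[lo, hi]` contains `truth`.
#' @param lower,upper interval endpoints, `lower <= upper` elementwise.
#' @export
coverage_95 <- function(lower, upper, truth) {
  if (length(lower) != length(upper)) stop("interval endpoint length mismatch")
  if (any(lower > upper)) stop("intervals must satisfy lower <= upper")
  mean(lower <= truth & truth <= upper)
}

#' @describeIn mc_statistics proportion of replications with `p < alpha`
#'   (strict: a p-value exactly at `alpha` does not reject).
#' @param p_values vector of two-sided p-values in `[0, 1]`.
#' @param alpha significance level (default 0.05).
#' @export
empirical_power <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  mean(p_values < alpha, na.rm = TRUE)
}

#' @describeIn mc_statistics proportion of replications classified
#'   `"converged"` among all attempted replications.
#' @param classifications character vector from [classify_convergence()].
#' @export
convergence_rate <- function(classifications) {
  if (length(classifications) == 0) stop("no classifications supplied")
  mean(classifications == "converged")
}

#' Summarize one design cell over its replications
#'
#' Applies the five Monte Carlo statistics per parameter over the
#' *converged* replications of one cell.  Power is computed for fixed
#' effects only; relative bias is skipped (NA) for parameters whose
#' generating value is zero.  Flags are attached where a statistic leaves
#' its conventional acceptance band: absolute relative bias above 5%, or
#' coverage outside [0.91, 0.98].
#'
#' @param fits list of `gmc_fit` objects (or the data frame produced by
#'   [collect_fits()]) from the same condition.
#' @param params the generating `gmc_params` for the cell.
#' @param label condition label carried into the output.
#' @return Object of class `gmc_summary`: list with `label`,
#'   `convergence_rate`, `n_converged`, `n_total`, and `stats`, a data
#'   frame with one row per parameter: `parameter`, `truth`, `mean_est`,
#'   `relative_bias`, `mse`, `coverage_95`, `power`, `mcse_mean` (Monte
#'   Carlo standard error of the mean estimate), `bias_flag`,
#'   `coverage_flag`.
#' @export
summarize_condition <- function(fits, params, label = "condition") {
  truth <- true_values(params)
  tab <- if (is.data.frame(fits)) fits else collect_fits(fits)
  cls <- tab$classification[!duplicated(tab$replication)]
  n_total <- length(cls)
  conv <- tab[tab$classification == "converged", , drop = FALSE]
  n_conv <- length(unique(conv$replication))
  out <- list(label = label, convergence_rate = mean(cls == "converged"),
              n_converged = n_conv, n_total = n_total)
  if (n_conv == 0) {
    out$stats <- NULL
    class(out) <- "gmc_summary"
    return(out)
  }
  pars <- intersect(names(truth), unique(tab$parameter))
  rows <- lapply(pars, function(p) {
    sub <- conv[conv$parameter == p, , drop = FALSE]
    tv <- truth[[p]]
    est <- sub$estimate
    rb <- if (tv != 0) relative_bias(est, tv) else NA_real_
    cov <- if (all(is.finite(sub$ci_lower)))
      coverage_95(sub$ci_lower, sub$ci_upper, tv) else NA_real_
    pow <- if (p %in% .fx_names) empirical_power(sub$p_value) else NA_real_
    data.frame(parameter = p, truth = tv, mean_est = mean(est),
               relative_bias = rb,
               mse = if (length(est) >= 2) mse(est, tv) else NA_real_,
               coverage_95 = cov,
               power = pow,
               mcse_mean = stats::sd(est) / sqrt(length(est)),
               bias_flag = !is.na(rb) && abs(rb) > 0.05,
               coverage_flag = !is.na(cov) && (cov < 0.91 || cov > 0.98))
  })
  out$stats <- do.call(rbind, rows)
  class(out) <- "gmc_summary"
  out
}

#' @export
print.gmc_summary <- function(x, ...) {
  cat(sprintf("condition '%s': convergence %.3f (%d/%d)\n", x$label,
              x$convergence_rate, x$n_converged, x$n_total))
  if (!is.null(x$stats)) {
    df <- x$stats
    df[2:8] <- lapply(df[2:8], round, 4)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Stack per-replication fits into a long data frame
#'
#' @param fits list of `gmc_fit` objects.
#' @return Data frame with columns `replication`, `parameter`, `estimate`,
#'   `se`, `z`, `p_value`, `ci_lower`, `ci_upper`, `classification`.
#' @export
collect_fits <- function(fits) {
  recs <- lapply(seq_along(fits), function(r) {
    df <- as.data.frame(fits[[r]])
    df$replication <- r
    df
  })
  out <- do.call(rbind, recs)
  out[c("replication", setdiff(names(out), "replication"))]
}

#' Tidy serialization of condition summaries
#'
#' One row per condition x parameter x statistic, suitable for CSV
#' exchange and downstream reshaping.
#'
#' @param summaries list of `gmc_summary` objects.
#' @return Data frame with columns `condition`, `parameter`, `statistic`,
#'   `value`.
#' @export
tidy_summaries <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    base <- data.frame(condition = s$label, parameter = "(model)",
                       statistic = c("convergence_rate", "n_converged",
                                     "n_total"),
                       value = c(s$convergence_rate, s$n_converged,
                                 s$n_total))
    if (is.null(s$stats)) return(base)
    long <- do.call(rbind, lapply(
      c("relative_bias", "mse", "coverage_95", "power"),
      function(st) data.frame(condition = s$label,
                              parameter = s$stats$parameter, statistic = st,
                              value = s$stats[[st]])))
    rbind(base, long)
  })
  do.call(rbind, rows)
}
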