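## Brute-force reference implementations used by the test suite.  These
## deliberately share no code with the estimation path: the covariance is
## assembled observation pair by observation pair and the density evaluated
## densely, with no blocking, profiling or Woodbury shortcuts.

#' Dense multivariate-normal log-likelihood (brute-force reference)
#'
#' Enumerates every observation pair and adds the covariance contributed by
#' shared group effects, shared individual effects, and the residual, then
#' evaluates the joint normal log-density of the whole outcome vector at
#' the given fixed effects.  Quadratic in memory and cubic in time; refuses
#' datasets above `max_obs` observations.
#'
#' @param data a long dataset.
#' @param beta fixed-effect vector in the order `gamma_000, gamma_001,
#'   gamma_010, gamma_100, gamma_101, gamma_110`.
#' @param vc a `gmc_varcomp` or named vector of the seven variances
#'   (covariances honoured via `sigma_r01` / `sigma_u_offdiag`).
#' @param max_obs dense feasibility guard (default 500).
#' @return The log-likelihood value.
#' @export
dense_loglik <- function(data, beta, vc, max_obs = 500L) {
  d <- as.data.frame(data)
  n <- nrow(d)
  if (n > max_obs) stop("dense oracle refuses more than ", max_obs, " rows")
  v <- unclass(vc)
  r01 <- if (!is.na(v["sigma_r01"])) v[["sigma_r01"]] else 0
  uoff <- if (!is.na(v["sigma_u_offdiag"])) v[["sigma_u_offdiag"]] else 0
  g2 <- matrix(c(v[["sigma2_r0"]], r01, r01, v[["sigma2_r1"]]), 2, 2)
  g3 <- diag(c(v[["sigma2_u00"]], v[["sigma2_u01"]], v[["sigma2_u10"]],
               v[["sigma2_u11"]]))
  g3[upper.tri(g3)] <- g3[lower.tri(g3)] <- uoff

  Sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    z3s <- c(1, d$x[s], d$time[s], d$time[s] * d$x[s])
    z2s <- c(1, d$time[s])
    for (t in seq_len(n)) {
      z3t <- c(1, d$x[t], d$time[t], d$time[t] * d$x[t])
      val <- 0
      if (d$group_id[s] == d$group_id[t]) {
        val <- val + drop(z3s %*% g3 %*% z3t)
        if (d$individual_id[s] == d$individual_id[t]) {
          z2t <- c(1, d$time[t])
          val <- val + drop(z2s %*% g2 %*% z2t)
          if (s == t) val <- val + v[["sigma2_e"]]
        }
      }
      Sigma[s, t] <- val
    }
  }
  mu <- beta[1] + beta[2] * d$z + beta[3] * d$x + beta[4] * d$time +
    beta[5] * d$time * d$z + beta[6] * d$time * d$x
  r <- d$y - mu
  ch <- chol(Sigma)
  w <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w^2))
}

#' Method-of-moments variance decomposition (ANOVA-style reference)
#'
#' Estimates the intercept-pathway variances at the three levels from mean
#' squares, independently of the likelihood machinery: pooled OLS removes
#' the fixed covariate effects, per-individual OLS lines give each
#' individual's time-0 intercept and the residual variance, and a one-way
#' unbalanced ANOVA of the intercepts over groups separates the
#' individual-level and group-level components (correcting the intercept
#' estimates for their OLS noise).
#'
#' @param data a long dataset with at least 2 groups and 2 individuals per
#'   group.
#' @return Named vector `c(sigma2_e, sigma2_r0, sigma2_u00)`.
#' @export
moment_decomposition <- function(data) {
  d <- as.data.frame(data)
  d <- d[order(d$group_id, d$individual_id, d$time), ]
  ols <- stats::lm(y ~ z + x + time + time:z + time:x, data = d)
  d$res <- stats::residuals(ols)

  T_ <- max(d$time) + 1
  tt <- seq.int(0, T_ - 1)
  Stt <- sum((tt - mean(tt))^2)
  R <- matrix(d$res, nrow = T_)              # occasions x individuals
  b <- as.numeric(crossprod(tt - mean(tt), R)) / Stt
  a <- colMeans(R) - b * mean(tt)
  rss <- colSums((R - rep(a, each = T_) - outer(tt, b))^2)
  m <- length(a)
  g_of_ind <- d$group_id[d$time == 0]
  J <- length(unique(g_of_ind))
  if (J < 2 || any(table(g_of_ind) < 2))
    stop("need at least 2 groups with 2+ individuals each")

  sigma2_e <- sum(rss) / (m * (T_ - 2))
  noise_a <- sigma2_e * (1 / T_ + mean(tt)^2 / Stt)

  g <- factor(g_of_ind)
  nj <- as.numeric(table(g))
  gm <- tapply(a, g, mean)
  ss_within <- sum((a - gm[g])^2)
  ms_within <- ss_within / (m - J)
  ss_between <- sum(nj * (gm - mean(a))^2)
  ms_between <- ss_between / (J - 1)
  n0 <- (m - sum(nj^2) / m) / (J - 1)   # unbalanced one-way ANOVA weight

  sigma2_r0 <- ms_within - noise_a
  sigma2_u00 <- (ms_between - ms_within) / n0
  c(sigma2_e = sigma2_e, sigma2_r0 = sigma2_r0, sigma2_u00 = sigma2_u00)
}
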