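test_that("build_group_covariance reproduces known structures", {
  d <- tiny_dataset(seed = 5, J = 2, rng = c(2, 2))
  g1 <- d[d$group_id == 1, ]
  th0 <- c(sigma2_e = 2, sigma2_r0 = 0, sigma2_r1 = 0, sigma2_u00 = 0,
           sigma2_u01 = 0, sigma2_u10 = 0, sigma2_u11 = 0)
  expect_equal(build_group_covariance(th0, g1), diag(2, nrow(g1)))
  # one individual, random intercept only, no residual: rank-1 all-ones
  one <- g1[g1$individual_id == 1, ]
  th1 <- th0; th1["sigma2_e"] <- 0; th1["sigma2_r0"] <- 1
  expect_equal(build_group_covariance(th1, one), matrix(1, 4, 4))
  expect_error(build_group_covariance(th0, d), "exactly one group")
})

test_that("build_group_covariance matches a brute-force simulation of the model", {
  # two individuals at fixed covariate values; compare V against the
  # empirical covariance of many direct draws from the model equations
  th <- c(sigma2_e = 0.7, sigma2_r0 = 1.2, sigma2_r1 = 0.4,
          sigma2_u00 = 0.5, sigma2_u01 = 0.2, sigma2_u10 = 0.3,
          sigma2_u11 = 0.15)
  xv <- c(-0.8, 1.3)
  g <- data.frame(group_id = 1, individual_id = rep(1:2, each = 4),
                  time = rep(0:3, 2), x = rep(xv, each = 4), z = 0, y = 0)
  V <- build_group_covariance(th, g)
  set.seed(99)
  R <- 2e5
  u <- matrix(rnorm(R * 4), R) %*% diag(sqrt(th[4:7]))
  Y <- matrix(0, R, 8)
  for (i in 1:2) {
    r0 <- rnorm(R, sd = sqrt(th[2])); r1 <- rnorm(R, sd = sqrt(th[3]))
    icpt <- u[, 1] + u[, 2] * xv[i] + r0
    slp <- u[, 3] + u[, 4] * xv[i] + r1
    for (t in 0:3)
      Y[, (i - 1) * 4 + t + 1] <- icpt + slp * t +
        rnorm(R, sd = sqrt(th[1]))
  }
  Vemp <- stats::cov(Y)
  expect_lt(max(abs(Vemp - V)), 0.06 * max(diag(V)))
})

test_that("profiled likelihood equals the dense MVN oracle on small datasets", {
  set.seed(1234)
  for (i in 1:20) {
    J <- sample(2:4, 1)
    d <- tiny_dataset(seed = 1000 + i, J = J, rng = c(2, 5))
    th <- c(runif(1, 0.5, 2.5), runif(1, 0.5, 2.5), runif(1, 0.1, 0.8),
            runif(4, 0.02, 0.5))
    pl <- profile_loglik(th, d)
    expect_equal(pl$status, 0L)
    dl <- dense_loglik(d, pl$beta, vc_from_theta(th))
    expect_equal(pl$loglik, dl, tolerance = 1e-8)
  }
})

test_that("profiled likelihood is invariant to group order and reduces to OLS", {
  d <- tiny_dataset(seed = 17, J = 4, rng = c(3, 5))
  th <- c(1.5, 1.0, 0.3, 0.2, 0.1, 0.05, 0.1)
  ll1 <- profile_loglik(th, d)$loglik
  perm <- d
  perm$group_id <- c(3, 1, 4, 2)[perm$group_id]  # relabel -> reorder blocks
  ll2 <- profile_loglik(th, perm)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-12)
  # all random variances zero: ordinary single-level normal likelihood
  s2 <- 1.7
  th0 <- c(s2, 0, 0, 0, 0, 0, 0)
  pl <- profile_loglik(th0, d)
  ols <- stats::lm(y ~ z + x + time + time:z + time:x, data = d)
  expect_equal(pl$loglik,
               sum(stats::dnorm(stats::residuals(ols), sd = sqrt(s2),
                                log = TRUE)),
               tolerance = 1e-10)
  # non-positive-definite theta is flagged infeasible, not an error
  expect_true(is.na(profile_loglik(c(-1, 0, 0, 0, 0, 0, 0), d)$loglik))
})

test_that("fit_ml recovers OLS in the zero-random-variance limit", {
  cond <- design_condition(500, c(10, 10), icc1(), base_seed = 1)
  d <- generate_dataset(deterministic_params(), cond, seed = 61)
  d$y <- d$y + rnorm(nrow(d), sd = sqrt(1.8))  # pure level-1 noise
  fit <- fit_ml(d, control = fit_control(se = FALSE))
  ols <- stats::lm(y ~ z + x + time + time:z + time:x, data = d)
  expect_equal(unname(fit$estimates[1:6]), unname(stats::coef(ols)[
    c("(Intercept)", "z", "x", "time", "z:time", "x:time")]),
    tolerance = 0.02)
  expect_equal(fit$estimates[["sigma2_e"]], 1.8, tolerance = 0.02)
  # the random-effect variances collapse toward zero
  expect_lt(max(abs(fit$estimates[c("sigma2_r0", "sigma2_r1", "sigma2_u00",
                                    "sigma2_u01", "sigma2_u10",
                                    "sigma2_u11")])), 0.05)
})

test_that("fit_ml recovers the generating parameters on one large replication", {
  cond <- design_condition(1000, c(10, 10), icc1(), base_seed = 1)
  d <- generate_dataset(params_for_condition(cond), cond, seed = 77)
  fit <- fit_ml(d)
  expect_equal(fit$classification, "converged")
  tv <- true_values(params_for_condition(cond))
  for (p in names(fit$estimates)[1:6])
    expect_lt(abs(fit$estimates[[p]] - tv[[p]]), 3 * fit$se[[p]])
  expect_true(all(fit$se > 0))
  expect_true(all(fit$ci_lower < fit$ci_upper))
})

test_that("estimates are scale-equivariant in the outcome units", {
  cond <- design_condition(150, c(10, 10), icc1())
  d <- generate_dataset(params_for_condition(cond), cond, seed = 8)
  f1 <- fit_ml(d, control = fit_control(se = FALSE))
  d2 <- d
  d2$y <- 2 * d$y
  f2 <- fit_ml(d2, control = fit_control(se = FALSE))
  expect_equal(unname(f2$estimates[1:6]), unname(2 * f1$estimates[1:6]),
               tolerance = 0.01)
  expect_equal(unname(f2$estimates[7:13]), unname(4 * f1$estimates[7:13]),
               tolerance = 0.01)
  # doubling the units shifts the maximized log-likelihood by -N log 2
  expect_equal(f2$loglik, f1$loglik - nrow(d) * log(2), tolerance = 1e-3)
})

test_that("data-driven failures yield classified non-converged fits, not errors", {
  d <- tiny_dataset(seed = 30, J = 4)
  one_group <- d[d$group_id == 1, ]
  f <- fit_ml(one_group)
  expect_s3_class(f, "gmc_fit")
  expect_false(f$converged)
  expect_equal(classify_convergence(f), "failed")
  flat <- d
  flat$y <- 1
  expect_equal(fit_ml(flat)$classification, "failed")
})

test_that("classification is consistent with the estimates of each fit", {
  # small groups make inadmissible (negative variance) optima common
  seen <- character(0)
  for (s in 1:10) {
    d <- tiny_dataset(seed = 500 + s, J = 8, rng = c(4, 7))
    f <- fit_ml(d)
    vars <- f$estimates[c("sigma2_e", "sigma2_r0", "sigma2_r1", "sigma2_u00",
                          "sigma2_u01", "sigma2_u10", "sigma2_u11")]
    expect_identical(f$admissible, all(vars >= 0))
    expected <- if (f$converged && f$admissible) "converged"
                else if (f$converged) "inadmissible" else "failed"
    expect_identical(classify_convergence(f), expected)
    if (f$classification == "converged") expect_true(all(f$se > 0))
    seen <- c(seen, f$classification)
  }
  # at this size both successful and negative-variance optima occur
  expect_gt(length(unique(seen)), 1)
})

test_that("free covariance structures nest the diagonal fit", {
  d <- tiny_dataset(seed = 44, J = 20, rng = c(4, 8))
  f0 <- fit_ml(d, control = fit_control(se = FALSE))
  f1 <- fit_ml(d, control = fit_control(se = FALSE, free_l2_cov = TRUE,
                                        free_l3_cov = TRUE))
  expect_true(all(c("sigma_r01", "sigma_u00_u01", "sigma_u10_u11") %in%
                    names(f1$estimates)))
  # the larger model cannot fit worse than its special case
  expect_gte(f1$loglik, f0$loglik - 1e-4)
})

test_that("the estimator agrees with an independent mixed-model implementation", {
  cond <- design_condition(150, c(10, 10), icc1())
  d <- generate_dataset(params_for_condition(cond), cond, seed = 8)
  fit <- fit_ml(d)
  expect_equal(fit$classification, "converged")
  d$ind <- interaction(d$group_id, d$individual_id)
  d$tx <- d$time * d$x
  lf <- lme4::lmer(y ~ z + x + time + time:z + tx + (1 + time || ind) +
                     (1 + x + time + tx || group_id),
                   data = d, REML = FALSE,
                   control = lme4::lmerControl(optimizer = "bobyqa"))
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$estimates[1:6]),
               unname(lme4::fixef(lf)[c("(Intercept)", "z", "x", "time",
                                        "z:time", "tx")]),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  lme4_vars <- c(vc$vcov[vc$grp == "Residual"],
                 vc$vcov[vc$grp == "ind" & vc$var1 == "(Intercept)"],
                 vc$vcov[vc$grp == "ind.1"],
                 vc$vcov[vc$grp == "group_id"],
                 vc$vcov[vc$grp == "group_id.1"],
                 vc$vcov[vc$grp == "group_id.2"],
                 vc$vcov[vc$grp == "group_id.3"])
  expect_equal(unname(fit$estimates[7:13]), lme4_vars, tolerance = 2e-3)
})

test_that("fits serialize to flat records and JSON", {
  d <- tiny_dataset(seed = 3, J = 10, rng = c(4, 6))
  f <- fit_ml(d)
  rec <- as.data.frame(f)
  expect_equal(nrow(rec), 13)
  expect_named(rec, c("parameter", "estimate", "se", "z", "p_value",
                      "ci_lower", "ci_upper", "classification"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$parameters), 13)
  expect_equal(parsed$classification, f$classification)
})
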