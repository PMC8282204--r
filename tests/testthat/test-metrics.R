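test_that("relative bias follows its defining formula", {
  expect_equal(relative_bias(c(2.0, 2.2), 2.0), 0.05)
  expect_equal(relative_bias(rep(0.37, 5), 0.37), 0)
  expect_equal(relative_bias(c(0.22, 0.24, 0.26), 0.2), 0.2)
  expect_error(relative_bias(c(0.1, 0.2), 0), "zero true value")
  expect_error(relative_bias(numeric(0), 1), "no estimates")
})

test_that("MSE equals mean squared deviation and the bias-variance identity", {
  expect_equal(mse(c(0.4, 0.6), 0.5), 0.01)
  expect_equal(mse(rep(0.5, 4), 0.5), 0)
  expect_equal(mse(c(1, 2, 3), 2), 2 / 3)
  expect_error(mse(1, 1), "at least 2")
  set.seed(11)
  for (i in 1:25) {
    est <- rnorm(50, mean = runif(1, 0.5, 2), sd = runif(1, 0.1, 1))
    truth <- runif(1, 0.5, 2)
    pop_var <- mean((est - mean(est))^2)
    expect_equal(mse(est, truth),
                 relative_bias(est, truth)^2 * truth^2 + pop_var,
                 tolerance = 1e-10)
  }
})

test_that("coverage counts closed intervals containing the truth", {
  expect_equal(coverage_95(c(0.1, 0.6), c(0.9, 0.8), 0.5), 0.5)
  expect_equal(coverage_95(rep(-Inf, 3), rep(Inf, 3), 0.5), 1)
  # degenerate interval exactly at the truth is covered (closed endpoints)
  expect_equal(coverage_95(0.5, 0.5, 0.5), 1)
  expect_error(coverage_95(1, 0, 0.5), "lower <= upper")
})

test_that("power uses strict rejection at alpha", {
  expect_equal(empirical_power(c(0.01, 0.04, 0.2)), 2 / 3)
  expect_equal(empirical_power(rep(0.05, 10)), 0)
  expect_equal(empirical_power(c(0.049, 0.051)), 0.5)
  expect_error(empirical_power(c(-0.1, 0.5)), "0, 1")
  # monotone non-increasing as alpha shrinks
  set.seed(5)
  p <- runif(200)
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  pw <- vapply(alphas, function(a) empirical_power(p, a), numeric(1))
  expect_true(all(diff(pw) <= 0))
})

test_that("convergence rate is the converged proportion", {
  cls <- c(rep("converged", 499), "failed")
  expect_equal(convergence_rate(cls), 0.998)
  expect_equal(convergence_rate(rep("converged", 7)), 1)
  expect_equal(convergence_rate(rep("inadmissible", 3)), 0)
  expect_error(convergence_rate(character(0)), "no classifications")
})

# Hand-built per-replication table emulating collect_fits() output.
fake_fits <- function(est_by_rep, se = 0.1, cls = NULL) {
  reps <- length(est_by_rep)
  if (is.null(cls)) cls <- rep("converged", reps)
  do.call(rbind, lapply(seq_len(reps), function(r) {
    est <- est_by_rep[[r]]
    data.frame(replication = r, parameter = names(est),
               estimate = unname(est), se = se,
               z = unname(est) / se,
               p_value = 2 * pnorm(-abs(unname(est) / se)),
               ci_lower = unname(est) - 1.959964 * se,
               ci_upper = unname(est) + 1.959964 * se,
               classification = cls[r])
  }))
}

test_that("condition summaries compose the individual statistics", {
  params <- generation_params(fixed_effects(), variance_components())
  tv <- true_values(params)
  set.seed(21)
  ests <- lapply(1:40, function(r) tv + rnorm(length(tv), sd = 0.1))
  tab <- fake_fits(ests)
  s <- summarize_condition(tab, params, label = "hand")
  expect_s3_class(s, "gmc_summary")
  expect_equal(s$convergence_rate, 1)
  g <- s$stats[s$stats$parameter == "gamma_001", ]
  est_vec <- vapply(ests, `[[`, numeric(1), "gamma_001")
  expect_equal(g$relative_bias, relative_bias(est_vec, 0.3))
  expect_equal(g$mse, mse(est_vec, 0.3))
  expect_equal(g$coverage_95,
               coverage_95(est_vec - 1.959964 * 0.1,
                           est_vec + 1.959964 * 0.1, 0.3))
  expect_equal(g$power,
               empirical_power(2 * pnorm(-abs(est_vec / 0.1))))
  # power is reported for fixed effects only
  expect_true(is.na(s$stats$power[s$stats$parameter == "sigma2_u00"]))
  # summaries are invariant to replication order
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(summarize_condition(perm, params, label = "hand")$stats,
               s$stats)
})

test_that("zero-valued true parameters are excluded from bias, kept elsewhere", {
  params <- generation_params(fixed_effects(gamma_001 = 0),
                              variance_components())
  tv <- true_values(params)
  set.seed(9)
  tab <- fake_fits(lapply(1:20, function(r) tv + rnorm(length(tv), sd = 0.1)))
  s <- summarize_condition(tab, params)
  row <- s$stats[s$stats$parameter == "gamma_001", ]
  expect_true(is.na(row$relative_bias))
  expect_false(is.na(row$mse))
  expect_false(is.na(row$coverage_95))
})

test_that("only converged replications enter the summaries", {
  params <- generation_params(fixed_effects(), variance_components())
  tv <- true_values(params)
  ests <- c(lapply(1:10, function(r) tv), list(tv + 100), list(tv - 100))
  cls <- c(rep("converged", 10), "inadmissible", "failed")
  s <- summarize_condition(fake_fits(ests, cls = cls), params)
  expect_equal(s$n_total, 12)
  expect_equal(s$n_converged, 10)
  expect_equal(s$convergence_rate, 10 / 12)
  # the wild non-converged estimates must not contaminate the cells
  expect_equal(s$stats$mean_est[s$stats$parameter == "gamma_000"], 0.5)
  s0 <- summarize_condition(fake_fits(list(tv), cls = "failed"), params)
  expect_null(s0$stats)
  expect_equal(s0$convergence_rate, 0)
})

test_that("Wald intervals with exact standard errors cover at the nominal rate", {
  params <- generation_params(fixed_effects(), variance_components())
  tv <- true_values(params)
  set.seed(33)
  sds <- 0.07
  tab <- fake_fits(lapply(1:500, function(r)
    tv + rnorm(length(tv), sd = sds)), se = sds)
  s <- summarize_condition(tab, params)
  binom3 <- 3 * sqrt(0.95 * 0.05 / 500)
  for (cov in s$stats$coverage_95)
    expect_lt(abs(cov - 0.95), binom3)
})

test_that("tidy serialization covers every condition, parameter and statistic", {
  params <- generation_params(fixed_effects(), variance_components())
  tv <- true_values(params)
  set.seed(2)
  s <- summarize_condition(fake_fits(lapply(1:8, function(r)
    tv + rnorm(length(tv), sd = 0.1))), params, label = "cell_a")
  tidy <- tidy_summaries(list(s))
  expect_named(tidy, c("condition", "parameter", "statistic", "value"))
  expect_equal(sum(tidy$statistic == "mse"), 13)
  expect_equal(tidy$value[tidy$statistic == "convergence_rate"], 1)
})
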