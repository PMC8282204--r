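#' Draw unbalanced group sizes
#'
#' Each group's number of individuals is drawn independently from the
#' discrete uniform distribution on the condition's inclusive range, so the
#' expected size equals the midpoint (the nominal group size).  Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param condition a `gmc_condition`.
#' @return Integer vector of length `n_groups`.
#' @export
draw_group_sizes <- function(condition) {
  stopifnot(inherits(condition, "gmc_condition"))
  rng <- condition$group_size_range
  if (rng[1] == rng[2]) return(rep(rng[1], condition$n_groups))
  # sample() would misread a length-1 vector, hence the explicit sequence
  sample(seq.int(rng[1], rng[2]), condition$n_groups, replace = TRUE)
}

## Cholesky factor of the group-level covariance (4x4) and the
## individual-level covariance (2x2), allowing nonzero covariances.
.g3_matrix <- function(vc) {
  g <- diag(unclass(vc)[c("sigma2_u00", "sigma2_u01", "sigma2_u10",
                          "sigma2_u11")])
  g[upper.tri(g)] <- g[lower.tri(g)] <- vc[["sigma_u_offdiag"]]
  g
}

.g2_matrix <- function(vc) {
  matrix(c(vc[["sigma2_r0"]], vc[["sigma_r01"]],
           vc[["sigma_r01"]], vc[["sigma2_r1"]]), 2, 2)
}

.safe_chol <- function(g, what) {
  if (all(g == 0)) return(matrix(0, nrow(g), nrow(g)))
  ev <- eigen(g, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
    stop(what, " covariance matrix is not positive semi-definite")
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Generate one long-format dataset from the three-level growth model
#'
#' Implements the combined model: for group `j`, individual `i`, occasion
#' `t = 0 .. T-1`,
#' \deqn{y_{tij} = (\gamma_{000} + \gamma_{001} z_j + u_{00j})
#'   + (\gamma_{010} + u_{01j}) x_{ij} + r_{0ij}
#'   + [(\gamma_{100} + \gamma_{101} z_j + u_{10j})
#'   + (\gamma_{110} + u_{11j}) x_{ij} + r_{1ij}]\, t + e_{tij},}
#' with `z_j, x_ij ~ N(0,1)`, mutually independent mean-zero normal random
#' effects with the supplied variances, and unbalanced group sizes drawn by
#' [draw_group_sizes()].  The same `(params, condition, seed)` triple
#' always yields a bit-identical dataset.
#'
#' @param params a `gmc_params` (see [generation_params()]).
#' @param condition a `gmc_condition`.
#' @param seed integer seed for this replication.
#' @param replication optional replication index stored as provenance.
#' @return A `data.frame` of class `gmc_dataset` with columns `group_id`,
#'   `individual_id`, `time`, `x`, `z`, `y`, rows ordered by group,
#'   individual, time; attributes `condition`, `seed`, `replication`.
#' @examples
#' cond <- design_condition(10, c(5, 15), icc_spec(0.45, 0.5, 0.05))
#' d <- generate_dataset(params_for_condition(cond), cond, seed = 42)
#' head(d)
#' @export
generate_dataset <- function(params, condition, seed, replication = NA_integer_) {
  stopifnot(inherits(params, "gmc_params"), inherits(condition, "gmc_condition"))
  vc <- params$varcomp
  fx <- unclass(params$fixed)
  T_ <- condition$n_timepoints

  set.seed(as.integer(seed))
  sizes <- draw_group_sizes(condition)
  J <- condition$n_groups
  n_ind <- sum(sizes)

  z_g <- stats::rnorm(J)
  u <- matrix(stats::rnorm(J * 4), J, 4) %*%
    t(.safe_chol(.g3_matrix(vc), "group-level"))      # u00, u01, u10, u11
  x_i <- stats::rnorm(n_ind)
  r <- matrix(stats::rnorm(n_ind * 2), n_ind, 2) %*%
    t(.safe_chol(.g2_matrix(vc), "individual-level")) # r0, r1

  gi <- rep.int(seq_len(J), sizes)            # group of each individual
  intercept_i <- fx[["gamma_000"]] + fx[["gamma_001"]] * z_g[gi] + u[gi, 1] +
    (fx[["gamma_010"]] + u[gi, 2]) * x_i + r[, 1]
  slope_i <- fx[["gamma_100"]] + fx[["gamma_101"]] * z_g[gi] + u[gi, 3] +
    (fx[["gamma_110"]] + u[gi, 4]) * x_i + r[, 2]

  tt <- rep.int(seq.int(0L, T_ - 1L), n_ind)
  io <- rep(seq_len(n_ind), each = T_)        # individual of each observation
  e <- stats::rnorm(n_ind * T_, sd = sqrt(vc[["sigma2_e"]]))
  y <- intercept_i[io] + slope_i[io] * tt + e

  ind_within <- sequence(sizes)               # individual id restarts per group
  out <- data.frame(group_id = gi[io],
                    individual_id = ind_within[io],
                    time = tt,
                    x = x_i[io],
                    z = z_g[gi][io],
                    y = y)
  attr(out, "condition") <- condition
  attr(out, "seed") <- as.integer(seed)
  attr(out, "replication") <- replication
  class(out) <- c("gmc_dataset", "data.frame")
  out
}

#' Validate the structural invariants of a long dataset
#'
#' Checks that every individual has exactly one row per occasion
#' `0 .. T-1`, that `z` is constant within group and `x` within individual,
#' and (when a condition is attached) that group sizes lie in the design
#' range.  Called by [fit_ml()] before estimation.
#'
#' @param data a long-format data frame (see [generate_dataset()]).
#' @return `data`, invisibly; errors on violation.
#' @export
validate_dataset <- function(data) {
  need <- c("group_id", "individual_id", "time", "x", "z", "y")
  if (!all(need %in% names(data)))
    stop("dataset must have columns ", paste(need, collapse = ", "))
  key <- interaction(data$group_id, data$individual_id, drop = TRUE)
  tt <- split(data$time, key)
  T_ <- length(tt[[1]])
  ok <- vapply(tt, function(v) length(v) == T_ &&
                 all(sort(v) == seq.int(0L, T_ - 1L)), logical(1))
  if (!all(ok))
    stop("every individual needs one row per occasion 0..T-1")
  if (any(vapply(split(data$z, data$group_id),
                 function(v) max(v) - min(v), numeric(1)) > 0))
    stop("z must be constant within group")
  if (any(vapply(split(data$x, key), function(v) max(v) - min(v),
                 numeric(1)) > 0))
    stop("x must be constant within individual")
  cond <- attr(data, "condition")
  if (!is.null(cond)) {
    sizes <- vapply(split(data$individual_id, data$group_id),
                    function(v) length(unique(v)), numeric(1))
    if (any(sizes < cond$group_size_range[1] |
            sizes > cond$group_size_range[2]))
      stop("group sizes fall outside the design range")
  }
  invisible(data)
}

#' Write / read the long-format CSV exchange schema
#'
#' Plain CSV with header `group_id,individual_id,time,x,z,y`; numeric
#' columns are written with 17 significant digits so a round trip is exact.
#'
#' @param data a long dataset.
#' @param path file path.
#' @return `write_long_csv`: `path` invisibly. `read_long_csv`: the
#'   dataset as a `gmc_dataset` data frame.
#' @export
write_long_csv <- function(data, path) {
  df <- as.data.frame(data)[c("group_id", "individual_id", "time",
                              "x", "z", "y")]
  for (col in c("x", "z", "y"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_long_csv
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(group_id = "integer",
                                             individual_id = "integer",
                                             time = "integer",
                                             x = "numeric", z = "numeric",
                                             y = "numeric"))
  class(df) <- c("gmc_dataset", "data.frame")
  df
}
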