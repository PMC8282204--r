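#' Run the Monte Carlo replications of one design cell
#'
#' For replication `r = 1 .. n_reps`: derive the replication seed
#' `replication_seed(base_seed, r)`, generate a dataset, fit it by
#' [fit_ml()], and classify the result.  Replications are independent and
#' identified by their seed alone, so the result is invariant to execution
#' order and to the number of workers.
#'
#' @param condition a `gmc_condition`.
#' @param params generating parameters; defaults to
#'   [params_for_condition()] applied to `condition`.
#' @param n_reps number of replications (defaults to the condition's
#'   `n_replications`).
#' @param workers forked parallel workers (1 = serial).
#' @param control a [fit_control()] for the estimator.
#' @param keep_fits keep the per-replication parameter table in the result.
#' @return List of class `gmc_run`: `summary` (a `gmc_summary`), `fits`
#'   (long data frame from [collect_fits()], or NULL), and `manifest`
#'   (seeds, classifications, timing — enough to re-run any single
#'   replication in isolation).
#' @examples
#' cond <- design_condition(10, c(5, 15), icc_spec(0.45, 0.5, 0.05),
#'                          n_replications = 3, base_seed = 11)
#' run <- run_condition(cond)
#' run$summary$convergence_rate
#' @export
run_condition <- function(condition, params = params_for_condition(condition),
                          n_reps = condition$n_replications, workers = 1L,
                          control = fit_control(), keep_fits = TRUE) {
  stopifnot(n_reps >= 1)
  seeds <- vapply(seq_len(n_reps), function(r)
    replication_seed(condition$base_seed, r), integer(1))
  one_rep <- function(r) {
    d <- generate_dataset(params, condition, seed = seeds[r], replication = r)
    fit <- fit_ml(d, control = control)
    df <- as.data.frame(fit)
    df$replication <- r
    df$loglik <- fit$loglik
    df
  }
  t0 <- Sys.time()
  recs <- if (workers > 1L)
    parallel::mclapply(seq_len(n_reps), one_rep, mc.cores = workers,
                       mc.preschedule = TRUE)
  else lapply(seq_len(n_reps), one_rep)
  bad <- vapply(recs, inherits, logical(1), what = "try-error")
  if (any(bad)) stop("worker failure in replications ",
                     paste(which(bad), collapse = ", "))
  fits <- do.call(rbind, recs)
  cls <- fits$classification[!duplicated(fits$replication)]
  summary <- summarize_condition(fits, params, label = condition$label)
  manifest <- list(label = condition$label, base_seed = condition$base_seed,
                   replication_seeds = seeds, n_reps = n_reps,
                   classifications = cls,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  structure(list(summary = summary,
                 fits = if (keep_fits) fits else NULL,
                 manifest = manifest), class = "gmc_run")
}

#' Simulation configuration
#'
#' The full description of a grid run: master seed, replication count, and
#' every overridable generating parameter.  [read_sim_config()] loads the
#' same structure from a YAML file (any subset of the fields of
#' `default_sim_config()`; unknown fields error).
#'
#' @param master_seed integer master seed.
#' @param n_replications replications per condition.
#' @param n_timepoints occasions per individual.
#' @param anchor_variance,anchor_level ICC anchoring (see [icc_spec()]).
#' @param fixed named list of [fixed_effects()] overrides.
#' @param variances named list of [variance_components()] overrides for the
#'   fields an ICC specification does not determine.
#' @param workers parallel workers for [run_grid()].
#' @return A list of class `gmc_config`.
#' @export
default_sim_config <- function(master_seed = 1L, n_replications = 500L,
                               n_timepoints = 4L, anchor_variance = 2.0,
                               anchor_level = 2L, fixed = list(),
                               variances = list(), workers = 1L) {
  structure(list(master_seed = as.integer(master_seed),
                 n_replications = as.integer(n_replications),
                 n_timepoints = as.integer(n_timepoints),
                 anchor_variance = anchor_variance,
                 anchor_level = as.integer(anchor_level),
                 fixed = fixed, variances = variances,
                 workers = as.integer(workers)),
            class = "gmc_config")
}

#' @rdname default_sim_config
#' @param path path to a YAML configuration file.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(default_sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(default_sim_config, raw)
}

#' Run the full 2 x 3 x 2 condition grid
#'
#' Runs every cell of [build_condition_grid()] under one configuration and,
#' when `out_dir` is given, writes the tidy per-cell summaries, the wide
#' publication-shaped tables (MSE, fixed-effect coverage, random-effect
#' coverage, power, relative bias, convergence), and a JSON run manifest.
#'
#' @param config a `gmc_config` (see [default_sim_config()]).
#' @param out_dir optional output directory for CSV tables and manifest.
#' @param conditions optional subset of condition indices (1..12) to run.
#' @param n_reps optional per-condition named or unnamed override of the
#'   replication count.
#' @param keep_fits keep per-replication tables in memory.
#' @return List of class `gmc_grid`: `summaries` (list of `gmc_summary`),
#'   `runs` (list of `gmc_run`), `manifest`.
#' @export
run_grid <- function(config = default_sim_config(), out_dir = NULL,
                     conditions = NULL, n_reps = NULL, keep_fits = FALSE) {
  stopifnot(inherits(config, "gmc_config"))
  grid <- build_condition_grid(config$master_seed, config$n_replications,
                               config$n_timepoints, config$anchor_variance,
                               config$anchor_level)
  idx <- if (is.null(conditions)) seq_along(grid) else as.integer(conditions)
  runs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    cond <- grid[[idx[k]]]
    reps <- if (is.null(n_reps)) cond$n_replications
            else n_reps[min(k, length(n_reps))]
    fx <- do.call(fixed_effects, config$fixed)
    params <- do.call(params_for_condition,
                      c(list(cond, fixed = fx), config$variances))
    message(sprintf("[growthmc] condition %d/%d (%s), %d replications",
                    k, length(idx), cond$label, reps))
    runs[[k]] <- run_condition(cond, params, n_reps = reps,
                               workers = config$workers,
                               keep_fits = keep_fits)
    runs[[k]]$condition <- cond
    runs[[k]]$params <- params
  }
  summaries <- lapply(runs, `[[`, "summary")
  manifest <- list(package_version = as.character(
                     utils::packageVersion("growthmc")),
                   master_seed = config$master_seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = unclass(config),
                   conditions = lapply(runs, function(r) r$manifest))
  out <- structure(list(summaries = summaries, runs = runs,
                        manifest = manifest, grid = grid[idx]),
                   class = "gmc_grid")
  if (!is.null(out_dir)) write_grid_outputs(out, out_dir)
  out
}

## One condition label -> (icc3, J, nominal n) bookkeeping for wide tables.
.cond_meta <- function(grid) {
  do.call(rbind, lapply(grid, function(cond) data.frame(
    condition = cond$label, icc3 = cond$icc$icc_level3,
    n_groups = cond$n_groups,
    group_size = round(mean(cond$group_size_range)))))
}

#' Wide publication-shaped table for one statistic
#'
#' Reshapes tidy summaries into the layout used to report three-level
#' simulation studies: parameter rows with an ICC sub-row each, and one
#' column per (number of groups, group size) combination.
#'
#' @param grid_result a `gmc_grid`.
#' @param statistic one of `"mse"`, `"coverage_95"`, `"power"`,
#'   `"relative_bias"`.
#' @param parameters which parameters to keep (default: all reported).
#' @return Data frame with columns `parameter`, `icc3`, then `J<j>_n<n>`
#'   value columns.
#' @export
wide_table <- function(grid_result,
                       statistic = c("mse", "coverage_95", "power",
                                     "relative_bias"),
                       parameters = NULL) {
  statistic <- match.arg(statistic)
  tidy <- tidy_summaries(grid_result$summaries)
  meta <- .cond_meta(grid_result$grid)
  df <- merge(tidy[tidy$statistic == statistic, ], meta, by = "condition")
  if (!is.null(parameters)) df <- df[df$parameter %in% parameters, ]
  df <- df[!is.na(df$value), ]
  if (nrow(df) == 0) return(data.frame())
  df$col <- sprintf("J%d_n%d", df$n_groups, df$group_size)
  cols <- unique(df$col[order(df$n_groups, df$group_size)])
  keys <- unique(df[c("parameter", "icc3")])
  keys <- keys[order(match(keys$parameter, c(.fx_names, .vc_diag_names)),
                     keys$icc3), ]
  out <- keys
  for (cl in cols)
    out[[cl]] <- mapply(function(p, i) {
      v <- df$value[df$parameter == p & df$icc3 == i & df$col == cl]
      if (length(v)) v[1] else NA_real_
    }, keys$parameter, keys$icc3)
  rownames(out) <- NULL
  out
}

#' Write all grid outputs
#'
#' @param grid_result a `gmc_grid`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_grid_outputs <- function(grid_result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tidy_summaries(grid_result$summaries),
                   file.path(out_dir, "summaries_tidy.csv"),
                   row.names = FALSE)
  tabs <- list(table_mse = wide_table(grid_result, "mse"),
               table_coverage_fixed =
                 wide_table(grid_result, "coverage_95", .fx_names),
               table_coverage_random =
                 wide_table(grid_result, "coverage_95", .vc_diag_names),
               table_power = wide_table(grid_result, "power", .fx_names),
               table_bias = wide_table(grid_result, "relative_bias"))
  for (nm in names(tabs))
    utils::write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  conv <- data.frame(condition = vapply(grid_result$summaries, `[[`,
                                        character(1), "label"),
                     convergence_rate = vapply(grid_result$summaries, `[[`,
                                               numeric(1),
                                               "convergence_rate"),
                     n_converged = vapply(grid_result$summaries, `[[`,
                                          numeric(1), "n_converged"),
                     n_total = vapply(grid_result$summaries, `[[`,
                                      numeric(1), "n_total"))
  utils::write.csv(conv, file.path(out_dir, "table_convergence.csv"),
                   row.names = FALSE)
  jsonlite::write_json(grid_result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-run a single replication from a manifest
#'
#' @param condition the `gmc_condition` of the cell.
#' @param replication replication index.
#' @param params generating parameters (default from the condition).
#' @param control estimator settings.
#' @return The `gmc_fit` for that replication, bit-identical to the one
#'   produced inside [run_condition()].
#' @export
rerun_replication <- function(condition, replication,
                              params = params_for_condition(condition),
                              control = fit_control()) {
  seed <- replication_seed(condition$base_seed, replication)
  d <- generate_dataset(params, condition, seed = seed,
                        replication = replication)
  fit_ml(d, control = control)
}
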