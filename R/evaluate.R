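#' Run one simulation replicate
#'
#' Draws `n_sample` records without replacement from the super-
#' population and analyses them with each requested method:
#' `no_missing` (the pre-amputation version of the same records),
#' `complete_case`, the two MICE-PMM strategies (`mice_all`,
#' `mice_primary`) and `smcfcs`. Imputation methods produce M completed
#' datasets, three cause-specific fits each, pooled per coefficient
#' with Rubin's rules (complete-data df = n_sample - 10). A method that
#' fails inside a replicate is recorded as an error and contributes no
#' rows.
#'
#' @param pop list as returned by [build_superpopulation()].
#' @param amputed the amputed super-population data.frame (aligned with
#'   `pop$data`).
#' @param cfg a [scenario_config()].
#' @param rep_seed integer seed for this replicate.
#' @param methods subset of
#'   `c("no_missing","complete_case","mice_all","mice_primary","smcfcs")`.
#' @param cycles chained-equation iterations for both imputation
#'   engines.
#' @param donors PMM donor-pool size.
#' @return data.frame of per-(method, cause, variable) rows with
#'   `qbar`, `se`, `df`, `ci_low`, `ci_high`; attribute `errors` is a
#'   named list of failure messages.
#' @export
run_replicate <- function(pop, amputed, cfg, rep_seed,
                          methods = c("no_missing", "complete_case",
                                      "mice_all", "mice_primary",
                                      "smcfcs"),
                          cycles = 10L, donors = 5L) {
  set.seed(rep_seed)
  idx <- sample.int(nrow(pop$data), cfg$n_sample)
  samp_full <- pop$data[idx, , drop = FALSE]
  samp_amp <- amputed[idx, , drop = FALSE]
  nu_com <- cfg$n_sample - 10L
  errors <- list()
  rows <- list()
  run <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
    } else {
      res$method <- name
      rows[[name]] <<- res
    }
  }
  if ("no_missing" %in% methods)
    run("no_missing", single_fit_table(samp_full,
                                       default_covariate_model()$names))
  if ("complete_case" %in% methods)
    run("complete_case", complete_case_fit(samp_amp))
  if ("mice_all" %in% methods)
    run("mice_all", pool_cause_specific(
      mice_pmm(samp_amp, "all_causes", M = cfg$M, cycles = cycles,
               donors = donors), nu_com))
  if ("mice_primary" %in% methods)
    run("mice_primary", pool_cause_specific(
      mice_pmm(samp_amp, "primary_only", M = cfg$M, cycles = cycles,
               donors = donors), nu_com))
  if ("smcfcs" %in% methods)
    run("smcfcs", pool_cause_specific(
      smcfcs_cr(samp_amp, M = cfg$M, cycles = cycles), nu_com))
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  attr(out, "errors") <- errors
  out
}

#' Performance metrics across replicates
#'
#' Summarises per-replicate pooled estimates against the super-
#' population "true" coefficients: relative bias (in percent, undefined
#' when the true value is zero), absolute bias, empirical coverage of
#' the 95% CIs (percent), mean estimated standard error, and Monte
#' Carlo standard errors for bias and coverage.
#'
#' @param results data.frame of stacked [run_replicate()] outputs with
#'   an added `rep` column.
#' @param true_values 10 x 3 matrix of true coefficients (rows named by
#'   covariate, columns = causes 1..3).
#' @return data.frame keyed by (method, cause, variable).
#' @export
compute_metrics <- function(results, true_values) {
  stopifnot(all(c("method", "cause", "variable", "qbar", "se",
                  "ci_low", "ci_high", "rep") %in% names(results)))
  key <- interaction(results$method, results$cause, results$variable,
                     drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    truth <- true_values[g$variable[1], g$cause[1]]
    R <- nrow(g)
    if (R < 2) stop("need at least 2 usable replicates per cell")
    mean_est <- mean(g$qbar)
    abs_bias <- mean_est - truth
    cover <- mean(g$ci_low <= truth & truth <= g$ci_high)
    data.frame(
      method = g$method[1], cause = g$cause[1], variable = g$variable[1],
      n_reps_used = R, mean_est = mean_est, abs_bias = abs_bias,
      relative_bias = if (truth != 0) 100 * abs_bias / truth else NA_real_,
      coverage = 100 * cover,
      mean_se = mean(g$se),
      mc_se_bias = stats::sd(g$qbar) / sqrt(R),
      mc_se_coverage = 100 * sqrt(cover * (1 - cover) / R),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$method, out$cause, match(out$variable,
                                         rownames(true_values))), ]
}

#' Run one scenario: super-population, amputation, replicates, metrics
#'
#' @param cfg a [scenario_config()].
#' @param methods methods to run (see [run_replicate()]).
#' @param cycles,donors imputation engine settings.
#' @param lib pattern library for amputation.
#' @param cov_model,betas data-generating model.
#' @param progress print per-replicate progress to stderr.
#' @return list with `metrics`, `results` (per-replicate rows),
#'   `true_values`, `pop_info` (censoring calibration), and `n_failed`
#'   per method.
#' @export
run_scenario <- function(cfg,
                         methods = c("no_missing", "complete_case",
                                     "mice_all", "mice_primary", "smcfcs"),
                         cycles = 10L, donors = 5L,
                         lib = default_pattern_library(),
                         cov_model = default_covariate_model(),
                         betas = default_coefficients(),
                         progress = FALSE) {
  pop <- build_superpopulation(cfg, cov_model, betas)
  amputed <- if (cfg$p_missing > 0)
    ampute_mar(pop$data, lib, cfg$p_missing,
               seed = derive_seed(cfg$seed, 0L))
  else pop$data
  res <- list()
  fail <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(cfg$n_reps)) {
    rr <- run_replicate(pop, amputed, cfg, derive_seed(cfg$seed, r),
                        methods, cycles, donors)
    errs <- attr(rr, "errors")
    for (nm in names(errs)) fail[nm] <- fail[nm] + 1L
    if (nrow(rr)) {
      rr$rep <- r
      res[[length(res) + 1L]] <- rr
    }
    if (progress && r %% 10 == 0)
      message(sprintf("  replicate %d/%d", r, cfg$n_reps))
  }
  results <- do.call(rbind, c(res, make.row.names = FALSE))
  list(metrics = compute_metrics(results, pop$true_values),
       results = results, true_values = pop$true_values,
       pop_info = list(lambda_c = pop$lambda_c,
                       realized_censoring = pop$realized_censoring),
       n_failed = fail)
}

#' Run the factorial scenario grid
#'
#' Iterates the scenario grid (default: 6 missingness proportions x 5
#' rate triplets = 30 scenarios), writing one pooled-results CSV per
#' scenario plus a combined `metrics.csv` and a JSON manifest to
#' `out_dir`. A scenario whose per-scenario CSV already exists is
#' skipped, making interrupted runs resumable.
#'
#' @param grid a [scenario_grid()] data.frame (its `configs` attribute
#'   supplies the per-scenario configurations).
#' @param out_dir output directory (created if absent).
#' @param methods,cycles,donors passed to [run_scenario()].
#' @param scaled_down optional named list of overrides (`n_super`,
#'   `n_reps`, `M`, `n_sample`) applied to every scenario for
#'   desk-scale runs; recorded in the manifest.
#' @return (invisibly) the combined metrics data.frame.
#' @export
run_grid <- function(grid = scenario_grid(), out_dir,
                     methods = c("no_missing", "complete_case",
                                 "mice_all", "mice_primary", "smcfcs"),
                     cycles = 10L, donors = 5L, scaled_down = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  configs <- attr(grid, "configs")
  all_metrics <- list()
  for (id in names(configs)) {
    cfg <- configs[[id]]
    if (!is.null(scaled_down))
      for (f in names(scaled_down)) cfg[[f]] <- scaled_down[[f]]
    path <- file.path(out_dir, paste0("pooled_", id, ".csv"))
    mpath <- file.path(out_dir, paste0("metrics_", id, ".csv"))
    if (file.exists(mpath)) {
      message("skipping completed scenario ", id)
      all_metrics[[id]] <- utils::read.csv(mpath, stringsAsFactors = FALSE)
      next
    }
    message("scenario ", id)
    sc <- run_scenario(cfg, methods, cycles, donors)
    sc$metrics$scenario <- id
    utils::write.csv(sc$results, path, row.names = FALSE)
    utils::write.csv(sc$metrics, mpath, row.names = FALSE)
    all_metrics[[id]] <- sc$metrics
  }
  metrics <- do.call(rbind, c(all_metrics, make.row.names = FALSE))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenarios = names(configs), methods = methods,
         cycles = cycles, donors = donors,
         scaled_down = if (is.null(scaled_down)) FALSE else scaled_down),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(metrics)
}
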