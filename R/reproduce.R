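#' Configuration of a full trade-off study
#'
#' Bundles every tunable of the pipeline.  The defaults are the study
#' conditions of the headline experiment: lattice `n = 8`, reachability
#' horizon `T = 7`, timeout penalty `t_theta = 70`, hitting-time cap
#' `2^n`, `m = 52` frontier bins, 10 asynchronous replicates, and
#' 10^4-cell rows for the segmentation sweeps on a 21-point probability
#' grid.
#'
#' @param n,horizon,cap,t_theta Metric parameters (see [rule_metrics()]).
#' @param m Frontier subinterval count (see [build_frontier()]).
#' @param p_values Probabilities at which the breaking degree is evaluated.
#' @param replicates Asynchronous replicates per rule.
#' @param n_cells Row length for segmentation sweeps.
#' @param sweep_grid Probability grid for the sweeps.
#' @param fit_degree Polynomial degree for the sweep fits.
#' @param seed Master seed.
#' @param boundary_seed Seed for the per-initial-row boundary pairs.
#' @param resample_boundary,union,weighted_pool Regime flags (boundary
#'   redrawn per step in [run_eca()]; union reachability; multiset-weighted
#'   emulator pool).
#' @return An `eca_study_config` list.
#' @export
study_config <- function(n = 8, horizon = 7, cap = max(t_theta, horizon),
                         t_theta = 70,
                         m = 52, p_values = seq(0.05, 0.95, by = 0.05),
                         replicates = 10, n_cells = 10000,
                         sweep_grid = seq(0, 0.95, by = 0.05), fit_degree = 4,
                         seed = 1L, boundary_seed = 1L,
                         resample_boundary = FALSE, union = FALSE,
                         weighted_pool = FALSE) {
  cfg <- list(n = as.integer(n), horizon = as.integer(horizon),
              cap = as.integer(cap), t_theta = as.numeric(t_theta),
              m = as.integer(m), p_values = as.numeric(p_values),
              replicates = as.integer(replicates),
              n_cells = as.integer(n_cells),
              sweep_grid = as.numeric(sweep_grid),
              fit_degree = as.integer(fit_degree),
              seed = as.integer(seed),
              boundary_seed = as.integer(boundary_seed),
              resample_boundary = isTRUE(resample_boundary),
              union = isTRUE(union), weighted_pool = isTRUE(weighted_pool))
  check_metric_sizes(cfg$n, cfg$horizon, cfg$cap)
  structure(cfg, class = "eca_study_config")
}

#' @rdname study_config
#' @param path File path for the JSON serialization.
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname study_config
#' @param config An `eca_study_config`.
#' @export
read_study_config <- function(path) {
  do.call(study_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Write a tibble as CSV with the producing config embedded as a comment
# header (read back with `read_study_csv`).
write_study_csv <- function(df, path, config) {
  hdr <- sprintf("# config: %s",
                 jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_study_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the full synchronous/asynchronous trade-off study
#'
#' Executes the pipeline end to end: synchronous `(U_N, E)` metrics for all
#' 256 rules, the lower-margin frontier, asynchronous metrics and the
#' breaking degree `D_B(p)` at each requested probability, the segmentation
#' sweep with its polynomial fits, and the regression of `D_B` on the
#' segment/rule ratio.  All tables are written as CSV (with the config
#' embedded as a comment header), summaries as JSON, and the result objects
#' are returned invisibly.  Identical seeds give byte-identical outputs.
#'
#' @param config An `eca_study_config`; the default reproduces the headline
#'   experiment (several minutes of compute).
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing files.
#' @param rules Rules to include (default all 256; the breaking degree is
#'   always normalized by 256).
#' @param quiet Suppress stage messages?
#' @return (Invisibly) a list: `sync`, `frontier`, `async` (per-p tibbles),
#'   `breaking` (tibble `p`, `D_B`, `n_below`), `sweep`, `fits`,
#'   `ratio_fit`, `config`, `timings`.
#' @examples
#' cfg <- study_config(n = 4, horizon = 3, cap = 16, p_values = 0.3,
#'                     replicates = 2, n_cells = 200, m = 8,
#'                     sweep_grid = seq(0, 1, 0.25))
#' res <- run_tradeoff_study(cfg, out_dir = NULL, rules = 0:15, quiet = TRUE)
#' @export
run_tradeoff_study <- function(config = study_config(), out_dir = "tradeoff-study",
                               rules = 0:255, quiet = FALSE) {
  stopifnot(inherits(config, "eca_study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed (config seed %d): %s",
                    stage, config$seed, conditionMessage(e)))
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("stage %-10s %8.2fs", stage, timings[[stage]])
    out
  }

  sync <- clock("metrics", rule_metrics(
    rules, n = config$n, horizon = config$horizon, cap = config$cap,
    t_theta = config$t_theta, p = 0, boundary_seed = config$boundary_seed))
  frontier <- clock("frontier", build_frontier(sync, m = config$m))

  seeds <- derive_seeds(config$seed, length(config$p_values) + 2)
  async <- list()
  breaking <- clock("breaking", {
    purrr::map_dfr(seq_along(config$p_values), function(i) {
      pts <- rule_metrics(
        rules, n = config$n, horizon = config$horizon, cap = config$cap,
        t_theta = config$t_theta, p = config$p_values[i],
        replicates = config$replicates,
        boundary_seed = config$boundary_seed, seed = seeds[i])
      async[[i]] <<- pts
      glance(breaking_degree(frontier, pts))
    })
  })

  sweep <- clock("sweep", sweep_segments(
    rules, p_grid = config$sweep_grid, n_cells = config$n_cells,
    seed = seeds[length(config$p_values) + 1]))
  fits <- clock("fits", fit_sweep(sweep, degree = config$fit_degree))
  ratio_fit <- clock("ratio", tryCatch(
    suppressWarnings(ratio_vs_breaking(sweep, breaking)),
    error = function(e) NULL))

  res <- list(sync = sync, frontier = frontier, async = async,
              breaking = breaking, sweep = sweep, fits = fits,
              ratio_fit = ratio_fit, config = config, timings = timings)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_study_config(config, file.path(out_dir, "config.json"))
    write_study_csv(sync, file.path(out_dir, "metrics_sync.csv"), config)
    write_study_csv(tidy(frontier), file.path(out_dir, "frontier.csv"), config)
    write_study_csv(dplyr::bind_rows(async),
                    file.path(out_dir, "metrics_async.csv"), config)
    write_study_csv(breaking, file.path(out_dir, "breaking.csv"), config)
    write_study_csv(tibble::as_tibble(sweep),
                    file.path(out_dir, "sweep.csv"), config)
    summary <- list(
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      D_B = stats::setNames(breaking$D_B, paste0("p", config$p_values)),
      fit_segments = list(coefficients = fits$segments$coefficients,
                          r_squared = fits$segments$r_squared),
      fit_rules = list(coefficients = fits$rules$coefficients,
                       r_squared = fits$rules$r_squared),
      ratio_fit_r_squared = if (!is.null(ratio_fit))
        ratio_fit$ratio$r_squared else NULL,
      timings = as.list(timings)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote artifacts to %s", out_dir)
  }
  invisible(res)
}
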