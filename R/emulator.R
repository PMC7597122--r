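#' Calibrate a synchronous multi-rule emulator of asynchronous dynamics
#'
#' Runs one asynchronous step of the base rule on a fresh seeded random row
#' of `n_cells` cells, segments the resulting transition against the base
#' rule, and turns the outcome into emulation parameters: the per-cell cut
#' probability `N1 / n_cells` and the pool of completed rules observed across
#' segments (with their segment frequencies).
#'
#' @inheritParams segment_transition
#' @param p Asynchrony (skip) probability used for the calibration step.
#' @param n_cells Row length for the calibration transition (default 10^4).
#' @param seed Seed for the random row, boundary and skip decisions.
#' @return An `eca_emulation_params` list: `base`, `p`, `n_cells`, `N1`,
#'   `N2`, `cut_probability`, `pool` (distinct rule numbers),
#'   `pool_weights` (segment frequencies), `seed`.
#' @export
calibrate_emulator <- function(base, p, n_cells = 10000, seed = NULL) {
  base <- parse_rule(base)
  p <- check_probability(p)
  n_cells <- as.integer(n_cells)
  if (n_cells < 3) abort("`n_cells` must be >= 3.")
  seg <- with_seed_opt(seed, {
    cfg <- random_configuration(n_cells)
    segment_transition(cfg, step_async(cfg, base, p)$cells, base = base)
  })
  counts <- table(seg$segments$rule)
  pool <- as.integer(names(counts))
  structure(
    list(base = base, p = p, n_cells = n_cells,
         N1 = seg$N1, N2 = seg$N2,
         cut_probability = seg$N1 / n_cells,
         pool = pool, pool_weights = as.integer(counts),
         seed = seed),
    class = "eca_emulation_params")
}

#' @export
print.eca_emulation_params <- function(x, ...) {
  cat(sprintf("<eca_emulation_params> base R%d, p = %g, %d cells\n",
              x$base, x$p, x$n_cells))
  cat(sprintf("  N1 = %d segments, N2 = %d rules, cut probability = %.4g\n",
              x$N1, x$N2, x$cut_probability))
  invisible(x)
}

#' @export
glance.eca_emulation_params <- function(x, ...) {
  tibble::tibble(base = x$base, p = x$p, n_cells = x$n_cells, N1 = x$N1,
                 N2 = x$N2, cut_probability = x$cut_probability)
}

#' Synchronous multi-rule emulation of asynchronous dynamics
#'
#' At each time step the row is cut into contiguous segments by i.i.d.
#' per-cell cut decisions with the calibrated cut probability (cell 1 always
#' starts a segment; a cut at cell i puts a boundary between i-1 and i).
#' Each segment is assigned a rule drawn uniformly from the calibrated pool
#' (or with segment-frequency weights when `weighted = TRUE`), and all cells
#' are then updated synchronously with their segment's rule, neighbours taken
#' across segment edges as usual.  Degenerate pools reduce exactly: a pool of
#' only the base rule reproduces repeated synchronous updating; a pool of
#' only rule 204 freezes the pattern.
#'
#' @param params An `eca_emulation_params` from [calibrate_emulator()].
#' @param initial An [eca_configuration] (boundary held fixed).
#' @param steps Number of time steps.
#' @param seed Optional seed for cuts and rule draws.
#' @param weighted Draw rules with segment-frequency weights instead of
#'   uniformly over the distinct pool rules?
#' @return An `eca_grid` ((steps + 1) x n matrix, time 0 first).
#' @export
emulate_multirule <- function(params, initial, steps, seed = NULL,
                              weighted = FALSE) {
  stopifnot(inherits(params, "eca_emulation_params"),
            inherits(initial, "eca_configuration"))
  steps <- as.integer(steps)
  n <- length(initial$cells)
  b <- initial$boundary
  pool_bits <- do.call(rbind, lapply(params$pool, rule_to_bits))
  w <- if (weighted) params$pool_weights else NULL
  grid <- matrix(0L, nrow = steps + 1, ncol = n)
  grid[1, ] <- initial$cells
  with_seed_opt(seed, {
    cells <- initial$cells
    if (steps > 0) for (t in seq_len(steps)) {
      cuts <- stats::runif(n) < params$cut_probability
      cuts[1] <- TRUE
      seg_id <- cumsum(cuts)
      seg_rule_idx <- sample.int(length(params$pool), max(seg_id),
                                 replace = TRUE, prob = w)
      left <- c(b[1], cells[-n])
      right <- if (n > 1) c(cells[-1], b[2]) else b[2]
      s <- 4L * left + 2L * cells + right
      cells <- pool_bits[cbind(seg_rule_idx[seg_id], s + 1L)]
      grid[t + 1, ] <- cells
    }
  })
  structure(grid, rule = params$base, p = params$p, boundary = b,
            regime = "emulated", class = c("eca_grid", "matrix", "array"))
}

#' Side-by-side asynchronous run and its multi-rule emulation
#'
#' Convenience wrapper: calibrates the emulator for (`base`, `p`), then runs
#' the asynchronous dynamics and the emulation from the same seeded initial
#' configuration, and collects the per-time density of 1-cells of both grids
#' (the quantitative summary under which the two regimes are compared).
#'
#' @inheritParams calibrate_emulator
#' @param steps Time steps for both runs.
#' @return A list with `params`, `async` and `emulated` (`eca_grid`s), and
#'   `densities` (tibble: `time`, `regime`, `density`).
#' @export
emulation_experiment <- function(base, p, n_cells = 10000, steps = 100,
                                 seed = 1L) {
  seeds <- derive_seeds(seed, 4)
  params <- calibrate_emulator(base, p, n_cells, seed = seeds[1])
  init <- random_configuration(n_cells, seed = seeds[2])
  async <- run_eca(init, base, steps, p = p, seed = seeds[3])
  emu <- emulate_multirule(params, init, steps, seed = seeds[4])
  dens <- tibble::tibble(
    time = rep(0:steps, 2),
    regime = rep(c("async", "emulated"), each = steps + 1),
    density = c(rowMeans(async), rowMeans(emu))
  )
  list(params = params, async = async, emulated = emu, densities = dens)
}
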