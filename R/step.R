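# Vectorized one-step update of a bit row with fixed boundary (b0, b1).
# With probability p each cell independently keeps its previous value
# instead of the rule output; no RNG is consumed when p is 0 or 1, so the
# degenerate regimes are deterministic.
step_bits <- function(cells, b0, b1, bits, p = 0) {
  n <- length(cells)
  if (p >= 1) return(cells)
  left <- c(b0, cells[-n])
  right <- if (n > 1) c(cells[-1], b1) else b1
  out <- bits[4L * left + 2L * cells + right + 1L]
  if (p > 0) {
    keep <- stats::runif(n) < p
    out[keep] <- cells[keep]
  }
  out
}

#' Single-step ECA dynamics
#'
#' `step_sync()` applies the rule simultaneously to every cell:
#' `a_i(t+1) = f_r(a_{i-1}(t), a_i(t), a_{i+1}(t))`, with the fixed boundary
#' pair supplying the missing neighbours of cells 1 and n.  `step_async()`
#' implements probabilistic asynchronous updating: each cell independently
#' keeps its previous state with probability `p` and takes the synchronous
#' output with probability `1 - p` (i.i.d. Bernoulli skip decisions per cell
#' per step).  `p = 0` reduces to `step_sync()` exactly; `p = 1` leaves the
#' row unchanged.  The boundary pair is never updated.
#'
#' @param config An [eca_configuration].
#' @inheritParams rule_to_bits
#' @param p Probability that a cell's update is skipped.
#' @param seed Optional seed for the skip decisions.
#' @return An [eca_configuration] with the updated cells and the same
#'   boundary.
#' @examples
#' cfg <- eca_configuration("010", boundary = c(0, 0))
#' step_sync(cfg, 90)$cells   # 1 0 1
#' @export
step_sync <- function(config, rule) {
  stopifnot(inherits(config, "eca_configuration"))
  bits <- rule_to_bits(rule)
  eca_configuration(
    step_bits(config$cells, config$boundary[1], config$boundary[2], bits),
    config$boundary
  )
}

#' @rdname step_sync
#' @export
step_async <- function(config, rule, p, seed = NULL) {
  stopifnot(inherits(config, "eca_configuration"))
  p <- check_probability(p)
  bits <- rule_to_bits(rule)
  cells <- with_seed_opt(seed,
    step_bits(config$cells, config$boundary[1], config$boundary[2], bits, p))
  eca_configuration(cells, config$boundary)
}

#' Space-time development of an ECA
#'
#' Iterates a rule from an initial configuration for `steps` time steps and
#' returns the space-time grid: row `t + 1` holds the cells at time `t`
#' (time 0 is the initial row).  The boundary pair is held fixed along the
#' trajectory by default; `resample_boundary = TRUE` redraws it uniformly at
#' every step instead.
#'
#' @inheritParams step_async
#' @param steps Number of time steps (`>= 0`).
#' @param resample_boundary Redraw the boundary pair at each step?
#' @return An `eca_grid`: an integer matrix of 0/1 with `steps + 1` rows,
#'   with attributes `rule`, `p` and `boundary`.
#' @examples
#' g <- run_eca(random_configuration(32, seed = 4), 18, steps = 16)
#' dim(g)
#' @export
run_eca <- function(config, rule, steps, p = 0, seed = NULL,
                    resample_boundary = FALSE) {
  stopifnot(inherits(config, "eca_configuration"))
  p <- check_probability(p)
  rule <- parse_rule(rule)
  bits <- rule_to_bits(rule)
  steps <- as.integer(steps)
  if (steps < 0) abort("`steps` must be >= 0.")
  grid <- matrix(0L, nrow = steps + 1, ncol = length(config$cells))
  grid[1, ] <- config$cells
  bnd <- config$boundary
  with_seed_opt(seed, {
    cells <- config$cells
    if (steps > 0) for (t in seq_len(steps)) {
      if (resample_boundary) bnd <- sample(0:1, 2, replace = TRUE)
      cells <- step_bits(cells, bnd[1], bnd[2], bits, p)
      grid[t + 1, ] <- cells
    }
  })
  structure(grid, rule = rule, p = p, boundary = config$boundary,
            class = c("eca_grid", class(grid)))
}

#' Read and write space-time grids as plain text
#'
#' The text format is one row per time step, each a string of '0'/'1'
#' characters.  `format = "pbm"` writes a portable bitmap (P1) header
#' instead, which image tools can open directly.
#'
#' @param grid An `eca_grid` or plain 0/1 matrix.
#' @param path File path.
#' @param format `"text"` or `"pbm"`.
#' @return `write_grid()`: the path, invisibly.  `read_grid()`: an integer
#'   matrix of 0/1.
#' @export
write_grid <- function(grid, path, format = c("text", "pbm")) {
  format <- match.arg(format)
  rows <- apply(grid, 1, paste, collapse = if (format == "pbm") " " else "")
  if (format == "pbm") {
    rows <- c("P1", paste(ncol(grid), nrow(grid)), rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  rows <- readLines(path)
  if (length(rows) >= 1 && rows[1] == "P1") {
    rows <- gsub(" ", "", rows[-(1:2)])
  }
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
}

#' Plot a space-time grid
#'
#' Time runs downwards; filled tiles are cells in state 1.
#'
#' @param object An `eca_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eca_grid <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(seq_len(nrow(object)) - 1L, ncol(object)),
    cell = rep(seq_len(ncol(object)), each = nrow(object)),
    state = as.integer(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$time,
                                   fill = factor(.data$state))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "cell", y = "time",
                  title = sprintf("R%d, p = %g", attr(object, "rule"),
                                  attr(object, "p")))
}
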