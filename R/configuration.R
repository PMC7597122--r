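#' ECA configurations with fixed boundary pairs
#'
#' A configuration is a row of `n` binary cells `a_1..a_n` together with a
#' fixed boundary pair `(a_0, a_{n+1})`.  The boundary cells are inputs to the
#' dynamics — the global map sends `B^(n+2)` to `B^n` — so they are not
#' themselves updated; by default they are held fixed along a trajectory.
#'
#' @param cells Cell bits, as an integer/logical vector or a "0101" string.
#' @param boundary The boundary pair `(a_0, a_{n+1})`, two bits.
#' @return An `eca_configuration`: a list with elements `cells` (integer
#'   vector) and `boundary` (integer pair).
#' @examples
#' eca_configuration("0110", boundary = c(1, 0))
#' @export
eca_configuration <- function(cells, boundary = c(0L, 0L)) {
  cells <- as_bits(cells, arg = "cells")
  if (length(cells) < 1) abort("`cells` must have length >= 1.")
  boundary <- as_bits(boundary, len = 2, arg = "boundary")
  structure(list(cells = cells, boundary = boundary),
            class = "eca_configuration")
}

#' @export
print.eca_configuration <- function(x, ...) {
  cat(sprintf("<eca_configuration> n = %d\n", length(x$cells)))
  cat(sprintf("  [%s] %s [%s]\n", x$boundary[1],
              bits_to_string(x$cells), x$boundary[2]))
  invisible(x)
}

#' @export
length.eca_configuration <- function(x) length(x$cells)

#' Seeded random configurations and boundary pairs
#'
#' Cells and boundary bits are i.i.d. uniform on \{0, 1\}.  With a `seed` the
#' draw is reproducible and the caller's RNG stream is left untouched; with
#' `seed = NULL` the current stream is used.
#'
#' @param n Number of cells (`n >= 1`).
#' @param seed Optional integer seed.
#' @param boundary Optional fixed boundary pair; if `NULL`, a random pair is
#'   drawn (after the cells, from the same stream).
#' @return `random_configuration()`: an [eca_configuration].
#'   `random_boundary()`: an integer pair.
#' @examples
#' random_configuration(8, seed = 1)
#' @export
random_configuration <- function(n, seed = NULL, boundary = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  n <- as.integer(n)
  with_seed_opt(seed, {
    cells <- sample(0:1, n, replace = TRUE)
    if (is.null(boundary)) boundary <- sample(0:1, 2, replace = TRUE)
    eca_configuration(cells, boundary)
  })
}

#' @rdname random_configuration
#' @export
random_boundary <- function(seed = NULL) {
  with_seed_opt(seed, sample(0:1, 2, replace = TRUE))
}

# The per-initial-row boundary pairs used by the exhaustive metric passes:
# one pair per initial row (2^n rows), drawn once from `boundary_seed` and
# reused across the reachable-set and hitting-time passes (and across rules
# and updating regimes, so synchronous and asynchronous runs see identical
# boundaries and are directly comparable).
boundary_matrix <- function(n, boundary_seed) {
  withr::with_seed(as.integer(boundary_seed),
    matrix(sample(0:1, 2^n * 2, replace = TRUE), ncol = 2))
}
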