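#' @importFrom rlang %||% abort warn .data
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
#' @importFrom stats lm coef predict runif
#' @importFrom Rcpp evalCpp
#' @useDynLib ecatradeoff, .registration = TRUE
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Coerce a bit sequence given as an integer/logical vector or a "0101" string.
# `len` (if not NULL) enforces an exact length.
as_bits <- function(x, len = NULL, arg = "x") {
  if (is.character(x) && length(x) == 1) {
    x <- as.integer(strsplit(x, "")[[1]])
  }
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    abort(sprintf("`%s` must contain only 0s and 1s.", arg))
  }
  if (!is.null(len) && length(x) != len) {
    abort(sprintf("`%s` must have length %d, not %d.", arg, len, length(x)))
  }
  x
}

bits_to_string <- function(bits) paste(bits, collapse = "")

# Integer code of a cell row, cell 1 as the most significant bit (matches the
# encoding used by the compiled trajectory engine).
bits_to_code <- function(bits) {
  n <- length(bits)
  sum(bits * 2^((n - 1):0))
}

code_to_bits <- function(code, n) {
  bitwAnd(bitwShiftR(as.integer(code), (n - 1):0), 1L)
}

# Evaluate `code` under `seed` when supplied, without disturbing the caller's
# RNG stream; with seed = NULL the current stream is used (and advanced).
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seeds for replicate/rule loops, derived from one master
# seed so that reordering the loop does not change any individual result.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, k))
}

check_probability <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single probability in [0, 1].")
  }
  as.numeric(p)
}
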