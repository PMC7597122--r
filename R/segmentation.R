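#' Segment a one-step transition into single-rule stretches
#'
#' Given a transition pair — a cell row with its boundary and the row one
#' step later — scan the cells left to right.  Cell `k` observes the output
#' `d_s = after[k]` for the neighbourhood index
#' `s = 4*before[k-1] + 2*before[k] + before[k+1]` (neighbours are the true
#' adjacent values of the `before` row, with the boundary pair at the ends).
#' Observations accumulate as constraints on a single rule; the first cell
#' whose observation conflicts with the current segment's constraints closes
#' the segment before that cell and opens a new one at it.  Each segment's
#' rule is completed by filling the undetermined outputs from the base rule,
#' so each segment is exactly explainable by one synchronously applied rule.
#' A transition generated by asynchronous updating of `base` therefore
#' segments into stretches whose completed rules are apparent rules of
#' `base` (see [apparent_rules()]).
#'
#' The first segment conceptually also contains the left-boundary cell
#' (index 0) as context; constraints only ever come from cells `1..n`, so
#' this bookkeeping affects neither the counts nor the completed rules.
#'
#' @param before The cell row at time `t`: an [eca_configuration], or a bit
#'   vector/string (then `boundary` supplies `(a_0, a_{n+1})`).
#' @param after The cell row at time `t + 1` (bit vector or string, same
#'   length).
#' @param base The base rule whose outputs fill undetermined entries.
#' @param boundary Boundary pair, used when `before` is not a configuration.
#' @return An `eca_segmentation`: a list with `segments` (tibble: `segment`,
#'   `start`, `end`, `length`, `rule`, `determined` list-column of partial
#'   output maps), counts `N1` (segments) and `N2` (distinct completed
#'   rules), and the input pair.  `tidy()` returns the segments tibble.
#' @examples
#' # a synchronous pair always yields one segment with the generating rule
#' cfg <- random_configuration(12, seed = 3)
#' seg <- segment_transition(cfg, step_sync(cfg, 18)$cells, base = 18)
#' seg$N1
#' @export
segment_transition <- function(before, after, base, boundary = c(0L, 0L)) {
  if (inherits(before, "eca_configuration")) {
    boundary <- before$boundary
    before <- before$cells
  } else {
    before <- as_bits(before, arg = "before")
    boundary <- as_bits(boundary, len = 2, arg = "boundary")
  }
  after <- as_bits(after, len = length(before), arg = "after")
  base <- parse_rule(base)
  raw <- cpp_segment(before, after, boundary[1], boundary[2],
                     rule_to_bits(base))
  determined <- lapply(seq_along(raw$start), function(j) {
    d <- raw$determined[, j]
    d[d < 0] <- NA_integer_
    stats::setNames(as.integer(d), paste0("d", 0:7))
  })
  segments <- tibble::tibble(
    segment = seq_along(raw$start),
    start = raw$start,
    end = raw$end,
    length = raw$end - raw$start + 1L,
    rule = raw$rule,
    determined = determined
  )
  structure(
    list(segments = segments, N1 = nrow(segments),
         N2 = length(unique(segments$rule)),
         base = base, before = before, after = after, boundary = boundary),
    class = "eca_segmentation")
}

#' @export
print.eca_segmentation <- function(x, ...) {
  cat(sprintf("<eca_segmentation> base R%d, n = %d: N1 = %d segments, N2 = %d distinct rules\n",
              x$base, length(x$before), x$N1, x$N2))
  cat(sprintf("  rules: %s\n", paste0("R", x$segments$rule, collapse = " ")))
  invisible(x)
}

#' @export
tidy.eca_segmentation <- function(x, ...) x$segments

#' @export
glance.eca_segmentation <- function(x, ...) {
  tibble::tibble(base = x$base, n = length(x$before), N1 = x$N1, N2 = x$N2)
}

#' Check that a segmentation reproduces its transition
#'
#' Applies each segment's completed rule synchronously to the segment's
#' member cells — neighbours are always the true adjacent `before` values,
#' also across segment edges — and tests whether the `after` row is
#' reproduced exactly.  This holds by construction for any result of
#' [segment_transition()]; it fails for tampered results.
#'
#' @param result An `eca_segmentation`.
#' @param rules Optional replacement vector of per-segment rule numbers
#'   (e.g. to test a constructed negative); defaults to the completed rules
#'   stored in `result`.
#' @return `TRUE` or `FALSE`.
#' @export
verify_segmentation <- function(result, rules = NULL) {
  stopifnot(inherits(result, "eca_segmentation"))
  rules <- rules %||% result$segments$rule
  if (length(rules) != result$N1) {
    abort("`rules` must supply one rule per segment.")
  }
  before <- result$before
  n <- length(before)
  b <- result$boundary
  left <- c(b[1], before[-n])
  right <- if (n > 1) c(before[-1], b[2]) else b[2]
  s <- 4L * left + 2L * before + right
  out <- integer(n)
  for (j in seq_len(result$N1)) {
    idx <- result$segments$start[j]:result$segments$end[j]
    bits <- rule_to_bits(rules[j])
    out[idx] <- bits[s[idx] + 1L]
  }
  identical(out, result$after)
}
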