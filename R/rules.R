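#' Wolfram rule coding for elementary cellular automata
#'
#' An elementary cellular automaton (ECA) rule maps each radius-1
#' neighbourhood `(x, y, z)` of binary cells to an output bit.  Indexing
#' neighbourhoods by `s = 4x + 2y + z`, the rule is coded by the integer
#' `r = sum(2^s * d_s)` over `s = 0..7`, where `d_s` is the output for
#' neighbourhood `s`.  There are 256 rules.  `rule_to_bits()` returns the
#' output table `(d_0, ..., d_7)` of a rule number; `bits_to_rule()` inverts
#' it; the two are a bijection over all 256 rules.
#'
#' Rule 204 plays a special role: its outputs equal the centre bit of every
#' neighbourhood, so it is the identity map on cell rows.
#'
#' @param rule An integer in `0:255`, or a string such as `"R18"`.
#' @param bits Eight bits `(d_0, ..., d_7)`, as an integer vector or a
#'   string such as `"01001000"`.
#' @return `rule_to_bits()`: an integer vector of length 8.
#'   `bits_to_rule()`: an integer rule number.
#' @examples
#' rule_to_bits(18)        # d_1 = d_4 = 1
#' bits_to_rule(c(0, 1, 0, 1, 1, 0, 1, 0))  # 90
#' @export
rule_to_bits <- function(rule) {
  rule <- parse_rule(rule)
  bitwAnd(bitwShiftR(rule, 0:7), 1L)
}

#' @rdname rule_to_bits
#' @export
bits_to_rule <- function(bits) {
  bits <- as_bits(bits, len = 8, arg = "bits")
  as.integer(sum(bits * 2^(0:7)))
}

#' @rdname rule_to_bits
#' @export
parse_rule <- function(rule) {
  if (is.character(rule)) rule <- sub("^[Rr]", "", rule)
  rule <- suppressWarnings(as.integer(rule))
  if (length(rule) != 1 || is.na(rule) || rule < 0 || rule > 255) {
    abort("`rule` must be a single integer in 0..255 (or an \"R18\"-style string).")
  }
  rule
}

# Output table of the identity rule: d_s equals the centre bit of s.
identity_bits <- function() {
  as.integer(bitwAnd(bitwShiftR(0:7, 1L), 1L))
}

#' The identity ECA rule number (204)
#'
#' The rule whose output for every neighbourhood equals the centre cell, i.e.
#' the identity map on rows.  A cell skipped by asynchronous updating behaves,
#' in the observed transition, as if this rule had been applied to it.
#' @return The integer 204.
#' @export
identity_rule <- function() bits_to_rule(identity_bits())

#' Tidy view of a rule's transition table
#'
#' @inheritParams rule_to_bits
#' @return A tibble with one row per neighbourhood: `s`, the neighbourhood
#'   bits `x`, `y`, `z` (left, centre, right), and the `output` bit.
#' @export
rule_table <- function(rule) {
  bits <- rule_to_bits(rule)
  s <- 0:7
  tibble::tibble(
    s = s,
    x = bitwAnd(bitwShiftR(s, 2L), 1L),
    y = bitwAnd(bitwShiftR(s, 1L), 1L),
    z = bitwAnd(s, 1L),
    output = bits
  )
}

#' Apparent rules of a base rule under asynchronous updating
#'
#' When a cell's update is skipped, the observed transition for its
#' neighbourhood `s` is the identity output (the centre bit of `s`) instead of
#' the base rule's `d_s`.  Over a whole row, the observed ("apparent") rule
#' therefore has, independently for each `s`, either the base output or the
#' identity output.  This enumerates all distinct rules obtainable that way.
#' The set always contains the base rule (nothing skipped) and rule 204
#' (everything skipped), and has exactly `2^H` elements, where `H` is the
#' Hamming distance between the output tables of the base rule and rule 204.
#'
#' @inheritParams rule_to_bits
#' @return A sorted integer vector of rule numbers.
#' @examples
#' apparent_rules(18)   # contains 18, 0, 90, 146, 128, 76, 204 among others
#' apparent_rules(204)  # just 204
#' @export
apparent_rules <- function(rule) {
  base <- rule_to_bits(rule)
  idn <- identity_bits()
  choices <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  rules <- apply(choices, 1, function(keep) {
    bits_to_rule(ifelse(keep, idn, base))
  })
  sort(unique(as.integer(rules)))
}

# Wolfram class annotations for the rules discussed alongside the apparent-
# rule calculus; descriptive labels only, never computed.
wolfram_class_notes <- function() {
  c(`18` = 3L, `0` = 1L, `90` = 3L, `146` = 3L, `128` = 1L, `76` = 2L, `204` = 2L)
}
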