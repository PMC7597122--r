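# Shared single-rule exhaustive pass.  Returns list(reachable, tau, U, E)
# for one realization of the regime (deterministic when p = 0).
metrics_pass <- function(rule, n, horizon, cap, t_theta, p, boundaries,
                         seed = NULL, union = FALSE) {
  if (union && horizon > cap) {
    abort("`union = TRUE` requires `horizon <= cap`.")
  }
  bits <- rule_to_bits(rule)
  with_seed_opt(seed,
    cpp_rule_metrics(bits, n, as.integer(horizon), as.integer(cap),
                     as.numeric(t_theta), p, boundaries, isTRUE(union)))
}

check_metric_sizes <- function(n, horizon, cap, full = TRUE) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  limit <- if (full) 12 else 20
  if (n > limit) {
    abort(sprintf(
      "n = %d requires enumerating 2^%d initial rows%s; this is refused above n = %d. Reduce `n`.",
      n, n, if (full) " and a 2^n x 2^n hitting-time table" else "", limit))
  }
  if (horizon < 1) abort("`horizon` must be >= 1.")
  if (cap < 1) abort("`cap` must be >= 1.")
}

#' Reachable states of an ECA rule
#'
#' Iterates a rule for exactly `horizon` steps from every one of the `2^n`
#' initial cell rows, each with its own seeded random boundary pair, and
#' collects the distinct states reached.  The count is the rule's
#' computational universality `U`; `U_N = U / 2^n` normalizes it.  With
#' `union = TRUE` the states visited at every `t <= horizon` are collected
#' instead of the states at exactly `horizon`.
#'
#' @inheritParams rule_to_bits
#' @param n Number of cells; the `2^n` enumeration is refused above `n = 20`.
#' @param horizon Iteration count `T` defining the reachable set.
#' @param p Skip probability; `0` is synchronous updating.
#' @param boundary_seed Seed for the per-initial-row boundary pairs.
#' @param union Collect states over all `t <= horizon` instead of exactly
#'   `horizon`?
#' @param seed Seed for the skip decisions when `p > 0`.
#' @return An `eca_reachability` object; `tidy()` gives one row per reachable
#'   state (`code`, `state` string), and the fields `U`, `U_N`, `rule`, `p`,
#'   `n`, `horizon` are stored on the object.
#' @examples
#' reachable_set(0, n = 2)$U     # 1
#' reachable_set(204, n = 2)$U   # 4
#' @export
reachable_set <- function(rule, n, horizon = 7, p = 0, boundary_seed = 1L,
                          union = FALSE, seed = NULL) {
  rule <- parse_rule(rule)
  p <- check_probability(p)
  check_metric_sizes(n, horizon, 1, full = FALSE)
  n <- as.integer(n)
  boundaries <- boundary_matrix(n, boundary_seed)
  codes <- with_seed_opt(seed,
    cpp_reachable_states(rule_to_bits(rule), n, as.integer(horizon), p,
                         boundaries, isTRUE(union)))
  structure(
    list(rule = rule, regime = if (p == 0) "sync" else "async", p = p,
         n = n, horizon = as.integer(horizon), boundary_seed = boundary_seed,
         union = isTRUE(union), states = codes,
         U = length(codes), U_N = length(codes) / 2^n),
    class = "eca_reachability")
}

#' @export
print.eca_reachability <- function(x, ...) {
  cat(sprintf("<eca_reachability> R%d (%s%s), n = %d, T = %d: U = %d, U_N = %.4g\n",
              x$rule, x$regime, if (x$p > 0) sprintf(", p = %g", x$p) else "",
              x$n, x$horizon, x$U, x$U_N))
  invisible(x)
}

#' @export
tidy.eca_reachability <- function(x, ...) {
  tibble::tibble(
    code = x$states,
    state = vapply(x$states, function(c) bits_to_string(code_to_bits(c, x$n)),
                   character(1))
  )
}

#' Reach time of a state and efficiency of a rule
#'
#' `tau()` is the summed time to reach state `X`: over all `2^n` initial rows
#' `Y`, the first time the trajectory from `Y` equals `X` within `cap` steps,
#' with the constant timeout penalty `t_theta` substituted for rows that
#' never reach `X`.  It is defined only for states in the reachable set.
#' `efficiency()` averages `tau` over the reachable states; smaller values
#' mean the rule reaches its reachable states faster.
#'
#' For the identity rule 204 every initial row is frozen, so every reachable
#' state `X` has `tau = 1 + t_theta * (2^n - 1)` (only the row `Y = X` hits,
#' at step 1) and the efficiency equals the same value.
#'
#' @inheritParams reachable_set
#' @param state The target state, as a bit vector, "0101" string, or integer
#'   code (cell 1 = most significant bit).
#' @param cap Hitting-time search window in steps.  The default equals the
#'   timeout penalty `t_theta`: a row either hits within `t_theta` steps or
#'   is charged exactly `t_theta`, so a hit can never cost more than a
#'   timeout.  Set `cap = 2^n` for the alternative reading in which the
#'   search runs over the whole state-space diameter.
#' @param t_theta Timeout penalty substituted for rows that never hit.
#' @return `tau()`: a single number.  `efficiency()`: a single number `E`.
#' @examples
#' tau(204, state = "00000000", n = 8, t_theta = 70)  # 1 + 70 * 255
#' efficiency(0, n = 4)                               # 2^4
#' @export
tau <- function(rule, state, n, horizon = 7, cap = max(t_theta, horizon),
                t_theta = 70, p = 0, boundary_seed = 1L, seed = NULL,
                union = FALSE) {
  rule <- parse_rule(rule)
  p <- check_probability(p)
  check_metric_sizes(n, horizon, cap)
  n <- as.integer(n)
  code <- if (is.character(state) || length(state) == n) {
    bits_to_code(as_bits(state, len = n, arg = "state"))
  } else if (is.numeric(state) && length(state) == 1) {
    as.integer(state)  # integer code, cell 1 = most significant bit
  } else {
    abort("`state` must be a length-n bit vector, a bit string, or an integer code.")
  }
  if (code < 0 || code >= 2^n) abort("`state` code out of range for this n.")
  boundaries <- boundary_matrix(n, boundary_seed)
  rec <- metrics_pass(rule, n, horizon, cap, t_theta, p, boundaries, seed,
                      union = union)
  idx <- match(code, rec$reachable)
  if (is.na(idx)) {
    abort(sprintf("State %s is not reachable for R%d (tau is undefined for non-reachable states).",
                  bits_to_string(code_to_bits(code, n)), rule))
  }
  rec$tau[idx]
}

#' @rdname tau
#' @export
efficiency <- function(rule, n, horizon = 7, cap = max(t_theta, horizon),
                       t_theta = 70, p = 0, boundary_seed = 1L, seed = NULL,
                       union = FALSE) {
  rule <- parse_rule(rule)
  p <- check_probability(p)
  check_metric_sizes(n, horizon, cap)
  n <- as.integer(n)
  boundaries <- boundary_matrix(n, boundary_seed)
  metrics_pass(rule, n, horizon, cap, t_theta, p, boundaries, seed,
               union = union)$E
}

#' Universality and efficiency for a set of rules
#'
#' The workhorse table builder: for each rule it runs the exhaustive
#' reachability and hitting-time passes and reports the universality `U`, its
#' normalization `U_N` and the efficiency `E`.  With `p = 0` (synchronous
#' updating) the computation is deterministic and done once per rule.  With
#' `p > 0` each rule is simulated `replicates` times with deterministically
#' derived sub-seeds, and `U`, `U_N` and `E` are the arithmetic means over
#' replicates.
#'
#' The per-initial-row boundary pairs come from `boundary_seed` alone, so
#' synchronous and asynchronous tables built with the same `boundary_seed`
#' are directly comparable (as the trade-off analysis requires).
#'
#' @param rules Integer vector of rule numbers (default all 256).
#' @inheritParams tau
#' @param replicates Number of stochastic replicates when `p > 0`.
#' @param seed Master seed for the skip decisions.
#' @return A tibble with columns `rule`, `regime`, `p`, `n`, `U`, `U_N`,
#'   `E`, `replicates`, `seed`.
#' @examples
#' rule_metrics(c(0, 204), n = 4, horizon = 3, t_theta = 70)
#' @export
rule_metrics <- function(rules = 0:255, n = 8, horizon = 7,
                         cap = max(t_theta, horizon), t_theta = 70, p = 0,
                         replicates = 1, boundary_seed = 1L, seed = 1L,
                         union = FALSE) {
  p <- check_probability(p)
  check_metric_sizes(n, horizon, cap)
  n <- as.integer(n)
  rules <- vapply(rules, parse_rule, integer(1))
  if (replicates < 1) abort("`replicates` must be >= 1.")
  replicates <- as.integer(replicates)
  boundaries <- boundary_matrix(n, boundary_seed)

  if (p == 0) {
    reps_used <- 1L
    recs <- lapply(rules, function(r)
      metrics_pass(r, n, horizon, cap, t_theta, 0, boundaries, union = union))
    U <- vapply(recs, function(x) as.numeric(x$U), numeric(1))
    E <- vapply(recs, function(x) x$E, numeric(1))
  } else {
    reps_used <- replicates
    subseeds <- matrix(derive_seeds(seed, length(rules) * replicates),
                       nrow = length(rules))
    agg <- lapply(seq_along(rules), function(i) {
      per <- lapply(seq_len(replicates), function(j)
        metrics_pass(rules[i], n, horizon, cap, t_theta, p, boundaries,
                     seed = subseeds[i, j], union = union))
      c(U = mean(vapply(per, function(x) as.numeric(x$U), numeric(1))),
        E = mean(vapply(per, function(x) x$E, numeric(1))))
    })
    U <- vapply(agg, `[[`, numeric(1), "U")
    E <- vapply(agg, `[[`, numeric(1), "E")
  }

  regime <- if (p == 0) "sync" else "async"
  seed_col <- if (p == 0) NA_integer_ else as.integer(seed)
  out <- tibble::tibble(
    rule = rules,
    regime = regime,
    p = p, n = n,
    U = U, U_N = U / 2^n, E = E,
    replicates = reps_used,
    seed = seed_col
  )
  attr(out, "params") <- list(n = n, horizon = as.integer(horizon),
                              cap = as.integer(cap), t_theta = t_theta,
                              boundary_seed = boundary_seed, union = union)
  out
}
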