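# Independent brute-force oracles, written against the definitions only —
# no shared code with the package internals beyond the public API.

# Output bit of `rule` for neighbourhood (l, c, r), straight from the base-2
# expansion of the rule number.
oracle_output <- function(rule, l, c, r) {
  (rule %/% 2^(4 * l + 2 * c + r)) %% 2
}

oracle_step <- function(cells, b0, b1, rule) {
  ext <- c(b0, cells, b1)
  vapply(seq_along(cells), function(i) {
    oracle_output(rule, ext[i], ext[i + 1], ext[i + 2])
  }, numeric(1))
}

oracle_code <- function(cells) sum(cells * 2^(rev(seq_along(cells)) - 1))

oracle_decode <- function(code, n) {
  vapply(seq_len(n), function(i) (code %/% 2^(n - i)) %% 2, numeric(1))
}

# The same boundary-pair convention the package documents: one pair per
# initial row, drawn from boundary_seed.
oracle_boundaries <- function(n, boundary_seed) {
  withr::with_seed(as.integer(boundary_seed),
    matrix(sample(0:1, 2^n * 2, replace = TRUE), ncol = 2))
}

# Full synchronous trajectory tables: reachable set at `horizon`, per-state
# summed hitting times within `cap` (penalty t_theta), and their mean.
oracle_metrics <- function(rule, n, horizon, cap, t_theta, boundary_seed) {
  nr <- 2^n
  bnd <- oracle_boundaries(n, boundary_seed)
  traj <- matrix(0L, nrow = nr, ncol = max(horizon, cap))
  for (y in seq_len(nr)) {
    cells <- oracle_decode(y - 1, n)
    for (t in seq_len(max(horizon, cap))) {
      cells <- oracle_step(cells, bnd[y, 1], bnd[y, 2], rule)
      traj[y, t] <- oracle_code(cells)
    }
  }
  reachable <- sort(unique(traj[, horizon]))
  tau <- vapply(reachable, function(X) {
    sum(vapply(seq_len(nr), function(y) {
      hit <- which(traj[y, seq_len(cap)] == X)
      if (length(hit) == 0) t_theta else min(hit)
    }, numeric(1)))
  }, numeric(1))
  list(reachable = reachable, tau = tau, U = length(reachable),
       E = mean(tau))
}

# Greedy left-to-right segmentation re-derived from the constraint rules:
# close the current segment whenever the next cell's observation contradicts
# the accumulated partial rule.
oracle_segment <- function(before, after, b0, b1, base) {
  n <- length(before)
  ext <- c(b0, before, b1)
  constraints <- rep(NA_integer_, 8)
  starts <- 1L
  rules <- integer(0)
  complete <- function(cns) {
    d <- vapply(0:7, function(s) {
      if (!is.na(cns[s + 1])) cns[s + 1] else (base %/% 2^s) %% 2
    }, numeric(1))
    sum(d * 2^(0:7))
  }
  for (k in seq_len(n)) {
    s <- 4 * ext[k] + 2 * ext[k + 1] + ext[k + 2]
    obs <- after[k]
    if (!is.na(constraints[s + 1]) && constraints[s + 1] != obs) {
      rules <- c(rules, complete(constraints))
      starts <- c(starts, k)
      constraints <- rep(NA_integer_, 8)
    }
    constraints[s + 1] <- obs
  }
  rules <- c(rules, complete(constraints))
  list(starts = starts, rules = rules, N1 = length(starts),
       N2 = length(unique(rules)))
}
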