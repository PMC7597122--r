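---
title: "Universality, efficiency, and the trade-off broken by asynchronous updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universality, efficiency, and the trade-off broken by asynchronous updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecatradeoff)
library(dplyr)
```

## The model

An elementary cellular automaton (ECA) is a row of `n` binary cells updated
by a radius-1 rule `f_r: B^3 -> B`.  Neighbourhoods `(x, y, z)` are indexed
by `s = 4x + 2y + z` and a rule is coded by the Wolfram number
`r = sum(2^s d_s)`, where `d_s` is the output bit for neighbourhood `s`;
there are 256 rules.  The row is bordered by a fixed boundary pair
`(a_0, a_{n+1})`: the global map sends `B^(n+2)` to `B^n`, so boundary cells
are inputs of the dynamics, not evolved state.

Two updating regimes are implemented.  Under synchronous updating every cell
applies the rule simultaneously.  Under probabilistic asynchronous updating
each cell independently *keeps* its previous state with probability `p` and
applies the rule with probability `1 - p`, i.i.d. per cell and per step.
`p = 0` recovers the synchronous dynamics bit for bit; `p = 1` freezes the
row, which is exactly the dynamics of rule 204 (the identity rule, whose
outputs equal the centre bit of every neighbourhood).

## Universality and efficiency

Both metrics are exhaustive over initial conditions.  For lattice size `n`,
every one of the `2^n` initial rows is given its own random boundary pair
(drawn once from `boundary_seed` and reused everywhere, so regimes are
compared on identical boundaries).

* **Universality** `U(r)` is the number of distinct states reached at
  exactly `T` steps from all `2^n` initial rows; `U_N = U / 2^n`.  A rule
  that collapses everything (rule 0) has `U_N = 1/2^n`; a permutation-like
  rule can have `U_N = 1`.
* **Reach time** `tau(X)` of a reachable state `X` sums, over all initial
  rows, the first time the trajectory equals `X` within a search window of
  `cap` steps, charging the constant timeout penalty `T_theta` to rows that
  never reach `X`.
* **Efficiency** `E(r)` is the mean of `tau` over the reachable states.
  Smaller is better: an efficient rule reaches its reachable repertoire
  quickly from everywhere.

Plotting `E` against `U_N` for all 256 synchronous rules traces a cloud
whose lower margin rises with universality: more universal rules are less
efficient.  `build_frontier()` formalizes the margin as a step function:
the `[0, 1]` universality axis is split into `m` bins (default `m = 52`),
each bin takes the minimum `E` of the rules inside it (empty bins are
filled with the overall maximum `E`), and the suffix minimum over bins makes
the function monotone non-decreasing.  `breaking_degree()` then counts the
rules whose *asynchronous* `(U_N, E)` point falls strictly below the
synchronous frontier at the bin of their own asynchronous universality, and
divides by 256.  This fraction, `D_B(p)`, is the degree to which
asynchronous updating breaks the synchronous trade-off.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `n` | 8 | cells | lattice size; metrics enumerate `2^n` rows |
| `horizon` (`T`) | 7 | steps | iteration count defining the reachable set |
| `t_theta` | 70 | steps | timeout penalty for rows that never hit |
| `cap` | `t_theta` | steps | hitting-time search window |
| `m` | 52 | bins | frontier subintervals |
| `p` | — | probability | per-cell, per-step skip probability |
| `replicates` | 10 | — | asynchronous realizations averaged per rule |
| `n_cells` | 10^4 | cells | row length for segmentation sweeps |
| `sweep_grid` | 0, 0.05, …, 0.95 | probability | sweep probabilities |

Two of these deserve their rationale spelled out.

**The search window equals the penalty.**  `cap` and `t_theta` are
independently configurable, but the default ties them together: a row either
hits within `t_theta` steps or is charged exactly `t_theta`.  If the window
is made much longer than the penalty (say `cap = 2^n` with `t_theta = 70`),
a late hit costs *more* than a timeout, and the efficiency measure inverts
its meaning: stochastic trajectories that wander and eventually hit
everything get penalized above deterministic ones that fail fast.  Under
that reading the asynchronous cloud sits *above* the synchronous frontier
and essentially no rule breaks the trade-off, which contradicts the
phenomenon the measure is designed to expose.  With
`cap = t_theta` a hit can never cost more than a failure, `E` is bounded by
`2^n * t_theta`, and mid-range asynchrony breaks the trade-off for roughly
35–40% of rules under the default replicate-mean protocol (see below).

**The sweep grid stops at 0.95.**  At `p = 1` no cell updates, the
transition is the identity, and the segmentation collapses to a single
segment with a single rule regardless of the base rule.  That endpoint is a
property of the degenerate identity transition, not of the asynchrony sweep:
including it inserts a discontinuous outlier at the end of otherwise smooth
convex curves and visibly degrades low-degree polynomial fits of the
rule-averaged curves, most strongly for the distinct-rule curve.  The default grid therefore covers
`{0.00, 0.05, ..., 0.95}`; pass an explicit grid including 1 to study the
endpoint itself.

## Asynchronous metric protocol

For `p > 0` the metrics are stochastic.  Each rule is simulated
`replicates` times (default 10) with sub-seeds derived deterministically
from the master seed, computing `(U_N, E)` per realization exactly as in the
synchronous case, and the arithmetic means are reported.  This is a
protocol choice: an alternative is to pool the reachable sets across
replicates (estimating the set of states reachable *with positive
probability*) before counting.  The two disagree materially — at `p = 0.3`
the replicate-mean protocol yields a `D_B` plateau of roughly 0.37 (as the
reproduction script measures), while union-pooling yields a substantially
larger fraction — so the package fixes the replicate-mean as the default
and exposes `replicates` explicitly rather than presenting either number
as canonical.

## Apparent rules and segmentation

When a cell's update is skipped, the observed transition of its
neighbourhood `s` is the identity output instead of `d_s`.  Over a row, the
observed ("apparent") rule has, independently per `s`, either the base or
the identity output — `apparent_rules()` enumerates the `2^H` possibilities,
where `H` is the Hamming distance between the base rule's output table and
rule 204's.

`segment_transition()` decomposes a one-step transition into maximal
left-to-right stretches each consistent with a *single* rule.  Scanning
cells `1..n`, each cell contributes the constraint `d_s = after[k]` with
`s` read from the true neighbours in the `before` row (boundary included;
segment edges never distort neighbourhoods).  The first cell whose
observation contradicts the accumulated constraints closes the current
segment *before* that cell and opens the next one at it.  Undetermined
outputs are completed from the base rule, so each segment's completed rule
reproduces the segment exactly (`verify_segmentation()` re-applies it and
checks).  The counts `N1` (segments) and `N2` (distinct completed rules)
are the raw material of the sweeps.  Two bookkeeping conventions are fixed
by the worked form of the decomposition: the first segment lists the left
boundary cell as context (constraints still come only from cells `1..n`),
and distinctness for `N2` is judged on completed rule numbers, not on
partial constraint maps.

## Multi-rule emulation

`calibrate_emulator()` segments one asynchronous transition of a
`n_cells`-cell row and converts it into emulation parameters: cut
probability `N1 / n_cells` and the pool of observed completed rules.
`emulate_multirule()` then runs synchronous multi-rule dynamics: each step,
i.i.d. cuts partition the row, each segment draws a rule from the pool
(uniform over distinct rules by default; segment-frequency weights behind
`weighted = TRUE`), and all cells update synchronously.  Degenerate pools
reduce exactly (single-rule pool = plain synchronous dynamics; identity
pool = frozen pattern).  The emulation is an approximation at the level of
qualitative pattern statistics: in density-trajectory comparisons the
weighted mode tracks the asynchronous run more closely than the uniform
mode, and neither matches within replicate-level sampling error.  That is a known limitation, not a target
the package tunes for.

## Sweeps and fits

`sweep_segments()` records, per rule and grid probability, one seeded
random row, one asynchronous step, one segmentation: `N1 / n_cells` and
`N2 / 256`.  Both rule-averaged curves are smooth and convex over the
default grid and are summarized by ordinary least-squares quartics
(`fit_polynomial()`, R² reported as `1 - SS_res / SS_tot`, defined as 0 for
a constant target).  The `#Segments/#Rules` ratio uses raw counts; its
linear regression against `D_B(p)` (`ratio_vs_breaking()`) requires the
caller to state the probability range — the default `[0.05, 0.55]` is
applied with a warning because the range over which the trade-off is broken
is itself an analysis choice.

## Seeding and numerical conventions

* One master seed drives everything; per-(rule, replicate) and per-(rule,
  probability) sub-seeds are derived by a seeded `sample.int`, so individual
  entries are reproducible in isolation and results do not depend on loop
  order.  Seeded helpers never disturb the caller's RNG stream.
* Boundary pairs are drawn once per initial row from `boundary_seed` and
  held fixed along trajectories (resampling per step is available as a flag
  in `run_eca()`); synchronous and asynchronous tables built with the same
  `boundary_seed` see identical boundaries.
* Frontier bins are half-open `[(k-1)/m, k/m)` with the last bin closed at
  1, so every universality value lands in exactly one bin; "below the
  frontier" is strict inequality.
* `p = 0` and `p = 1` consume no random numbers, so the degenerate regimes
  are exactly deterministic.
* Exhaustive metrics refuse `n > 12` (the hitting-time pass stores a
  `2^n x 2^n` table); the reachable set alone is available up to `n = 20`.

## What the tests do and do not show

The test suite checks the worked small cases exactly (closed-form reach
times, the hand-derived segmentation prefix, the `n = 2` universality
counts), verifies the full-scale frontier properties at `n = 8` with all
256 rules, and cross-checks reachability, reach times, efficiency and
segmentation against independent brute-force oracles at small sizes
(`n <= 4`, 30-cell rows).  Stochastic claims are tested at the default
study conditions — breaking degree at `p = 0.3` with 10 replicates,
sweep fits with `10^4`-cell rows — with seeds fixed inside the tests.
These conditions are exhaustive over initial states, so there is no hidden
sampling of initial conditions; what the tests do *not* establish is
behaviour at lattice sizes beyond the enumerable range, under periodic or
evolving boundaries (out of scope by design), or for order-based (rather
than probabilistic) asynchronous updating.

## Known limitations

* `E` depends on the `cap`/`t_theta` convention; both are exposed, and the
  default is argued above rather than self-evident.
* The asynchronous replicate-aggregation protocol materially affects
  `D_B`; the replicate-mean default is a fixed choice, not a unique answer.
* The multi-rule emulation reproduces qualitative density behaviour only.
* Segmentation is greedy left-to-right by construction; it does not attempt
  minimum-segment decompositions.
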