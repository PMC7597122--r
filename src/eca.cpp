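#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One synchronous/asynchronous update of a cell row with fixed boundary
// (b0, b1).  `bits` is the 8-entry rule output table indexed by
// s = 4*left + 2*centre + right.  With probability p a cell keeps its
// previous state (no RNG is consumed when p is exactly 0 or 1, so the
// degenerate regimes are bit-for-bit deterministic).  Returns the integer
// code of the new row with cell 1 as the most significant bit.
static inline int step_row(const int* cells, int* out, int n, int b0, int b1,
                           const int* bits, double p) {
  int code = 0;
  for (int i = 0; i < n; ++i) {
    int l = (i == 0) ? b0 : cells[i - 1];
    int r = (i == n - 1) ? b1 : cells[i + 1];
    int v;
    if (p >= 1.0) {
      v = cells[i];
    } else {
      v = bits[4 * l + 2 * cells[i] + r];
      if (p > 0.0 && unif_rand() < p) v = cells[i];
    }
    out[i] = v;
    code = (code << 1) | v;
  }
  return code;
}

static inline void decode_row(int code, int n, int* cells) {
  for (int i = 0; i < n; ++i) cells[i] = (code >> (n - 1 - i)) & 1;
}

// Exhaustive universality/efficiency pass for one rule: iterate every one of
// the 2^n initial rows (each with its own fixed boundary pair, row y of
// `boundaries`) for max(horizon, cap) steps, recording the state at time
// `horizon` (the reachable set) and the first hitting time of every state
// within `cap` steps.  tau(X) sums hitting times over rows, substituting
// t_theta for rows that never hit X; E averages tau over reachable states.
// [[Rcpp::export]]
List cpp_rule_metrics(IntegerVector bits, int n, int horizon, int cap,
                      double t_theta, double p, IntegerMatrix boundaries,
                      bool union_mode) {
  const int nrows = 1 << n;
  const int tmax = std::max(horizon, cap);
  std::vector<int> fh((size_t)nrows * nrows, -1);
  std::vector<int> at_horizon(nrows);
  std::vector<int> cur(n), nxt(n);

  for (int y = 0; y < nrows; ++y) {
    decode_row(y, n, cur.data());
    const int b0 = boundaries(y, 0), b1 = boundaries(y, 1);
    for (int t = 1; t <= tmax; ++t) {
      int code = step_row(cur.data(), nxt.data(), n, b0, b1, &bits[0], p);
      std::swap(cur, nxt);
      if (t <= cap && fh[(size_t)y * nrows + code] < 0)
        fh[(size_t)y * nrows + code] = t;
      if (t == horizon) at_horizon[y] = code;
    }
  }

  std::vector<char> seen(nrows, 0);
  std::vector<int> reach;
  if (union_mode) {
    // states visited by any row at t <= horizon (horizon <= cap is enforced
    // by the caller in this mode, so the first-hit table covers them)
    for (int X = 0; X < nrows; ++X) {
      for (int y = 0; y < nrows; ++y) {
        int h = fh[(size_t)y * nrows + X];
        if (h >= 0 && h <= horizon) { reach.push_back(X); break; }
      }
    }
  } else {
    for (int y = 0; y < nrows; ++y)
      if (!seen[at_horizon[y]]) { seen[at_horizon[y]] = 1; reach.push_back(at_horizon[y]); }
    std::sort(reach.begin(), reach.end());
  }

  NumericVector tau(reach.size());
  for (size_t j = 0; j < reach.size(); ++j) {
    double s = 0;
    const int X = reach[j];
    for (int y = 0; y < nrows; ++y) {
      int h = fh[(size_t)y * nrows + X];
      s += (h < 0) ? t_theta : h;
    }
    tau[j] = s;
  }
  double E = 0;
  for (size_t j = 0; j < reach.size(); ++j) E += tau[j];
  E /= (double)reach.size();

  return List::create(_["U"] = (int)reach.size(),
                      _["reachable"] = wrap(reach),
                      _["tau"] = tau,
                      _["E"] = E);
}

// Reachable set only (no hitting-time matrix, so memory stays O(2^n)).
// If union_mode, collect the states visited at every t = 1..horizon instead
// of the states at exactly t = horizon.  Returns sorted unique codes.
// [[Rcpp::export]]
IntegerVector cpp_reachable_states(IntegerVector bits, int n, int horizon,
                                   double p, IntegerMatrix boundaries,
                                   bool union_mode) {
  const int nrows = 1 << n;
  std::vector<char> seen(nrows, 0);
  std::vector<int> cur(n), nxt(n);
  for (int y = 0; y < nrows; ++y) {
    decode_row(y, n, cur.data());
    const int b0 = boundaries(y, 0), b1 = boundaries(y, 1);
    int code = y;
    for (int t = 1; t <= horizon; ++t) {
      code = step_row(cur.data(), nxt.data(), n, b0, b1, &bits[0], p);
      std::swap(cur, nxt);
      if (union_mode) seen[code] = 1;
    }
    if (!union_mode) seen[code] = 1;
  }
  std::vector<int> reach;
  for (int c = 0; c < nrows; ++c) if (seen[c]) reach.push_back(c);
  return wrap(reach);
}

// Greedy left-to-right segmentation of a one-step transition against a base
// rule.  Each cell k (1-based) observes d_s = after[k] for
// s = 4*before[k-1] + 2*before[k] + before[k+1], neighbours taken from the
// true `before` row (boundary b0/b1 at the ends).  The first cell whose
// observation conflicts with the current segment's accumulated constraints
// starts a new segment.  Undetermined outputs are completed from the base
// rule.  Returns 1-based starts/ends, the completed rule per segment, and
// the determined partial maps (-1 = undetermined) as an 8 x N1 matrix.
// [[Rcpp::export]]
List cpp_segment(IntegerVector before, IntegerVector after, int b0, int b1,
                 IntegerVector base_bits) {
  const int n = before.size();
  std::vector<int> starts;
  std::vector< std::array<int, 8> > dets;
  std::array<int, 8> cur;
  cur.fill(-1);
  int segstart = 1;
  for (int k = 0; k < n; ++k) {
    int l = (k == 0) ? b0 : before[k - 1];
    int r = (k == n - 1) ? b1 : before[k + 1];
    int s = 4 * l + 2 * before[k] + r;
    int obs = after[k];
    if (cur[s] >= 0 && cur[s] != obs) {
      starts.push_back(segstart);
      dets.push_back(cur);
      segstart = k + 1;  // conflicting cell (1-based) opens the next segment
      cur.fill(-1);
    }
    cur[s] = obs;
  }
  starts.push_back(segstart);
  dets.push_back(cur);

  const int nseg = (int)starts.size();
  IntegerMatrix det(8, nseg);
  IntegerVector rule_num(nseg), start_v(nseg), end_v(nseg);
  for (int j = 0; j < nseg; ++j) {
    start_v[j] = starts[j];
    end_v[j] = (j + 1 < nseg) ? starts[j + 1] - 1 : n;
    int rn = 0;
    for (int s = 0; s < 8; ++s) {
      det(s, j) = dets[j][s];
      int d = dets[j][s] >= 0 ? dets[j][s] : base_bits[s];
      rn += d << s;
    }
    rule_num[j] = rn;
  }
  return List::create(_["start"] = start_v, _["end"] = end_v,
                      _["rule"] = rule_num, _["determined"] = det);
}
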