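#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact solver for the segment ordering/orientation problem on one connected
// component. Maximizes total weight of compatible edges; an edge (u_i, v_j)
// is compatible iff it connects the trailing end of the earlier segment to
// the leading end of the later segment under the arrangement.
//
// Dynamic program over placement states: each segment is unplaced (0),
// placed forward (1) or placed reverse (2); segments are appended left to
// right, and an edge is scored when its second endpoint is placed (the
// relative order of its endpoints is then fixed). 3^n states.
//
// Objective is lexicographic: (total compatible weight, number of satisfied
// reference-concordant edges, number of forward segments). The second and
// third terms implement deterministic tie-breaking toward arrangements that
// keep reference-concordant evidence satisfied and invert as few segments
// as possible.

static inline bool f_val(bool head_side, bool y) {
  // orientation-function value of an endpoint: f(head) = y, f(tail) = 1 - y
  return head_side ? y : !y;
}

// [[Rcpp::export(name = ".dp_arrange")]]
List dp_arrange(int n, IntegerVector ea, IntegerVector eb,
                LogicalVector head_a, LogicalVector head_b,
                NumericVector w, LogicalVector conc) {
  if (n < 1) stop("empty component");
  if (n > 16) stop("component too large for exact placement DP (n > 16)");
  const int m = ea.size();

  std::vector<int64_t> pow3(n + 1);
  pow3[0] = 1;
  for (int i = 1; i <= n; ++i) pow3[i] = pow3[i - 1] * 3;
  const int64_t S = pow3[n];

  // adjacency: for each vertex, incident edges
  std::vector<std::vector<int>> inc(n);
  for (int e = 0; e < m; ++e) {
    if (ea[e] < 0 || ea[e] >= n || eb[e] < 0 || eb[e] >= n || ea[e] == eb[e])
      stop("bad edge endpoint");
    inc[ea[e]].push_back(e);
    inc[eb[e]].push_back(e);
  }

  std::vector<double> val(S, -1.0);
  std::vector<int32_t> cc(S, 0);
  std::vector<int16_t> fw(S, 0);
  val[0] = 0.0;

  std::vector<int> digit(n);
  double bestV = -1.0; int32_t bestC = 0; int16_t bestF = 0; int64_t bestS = -1;

  for (int64_t s = 0; s < S; ++s) {
    if (val[s] < 0) continue;
    int64_t t = s;
    int unplaced = 0;
    for (int i = 0; i < n; ++i) { digit[i] = t % 3; t /= 3; if (digit[i] == 0) ++unplaced; }
    if (unplaced == 0) {
      if (val[s] > bestV ||
          (val[s] == bestV && (cc[s] > bestC || (cc[s] == bestC && fw[s] > bestF)))) {
        bestV = val[s]; bestC = cc[s]; bestF = fw[s]; bestS = s;
      }
      continue;
    }
    for (int v = 0; v < n; ++v) {
      if (digit[v] != 0) continue;
      for (int d = 1; d <= 2; ++d) {
        const bool yv = (d == 1);
        double gain = 0.0; int32_t cgain = 0;
        for (int k = 0; k < (int)inc[v].size(); ++k) {
          const int e = inc[v][k];
          const int u = (ea[e] == v) ? eb[e] : ea[e];
          const int du = digit[u];
          if (du == 0) continue; // scored when the later endpoint is placed
          const bool yu = (du == 1);
          const bool fu = f_val(ea[e] == v ? (bool)head_b[e] : (bool)head_a[e], yu);
          const bool fv = f_val(ea[e] == v ? (bool)head_a[e] : (bool)head_b[e], yv);
          // u placed earlier => u before v; compatible iff f(u.)=0 and f(v.)=1
          if (!fu && fv) { gain += w[e]; if (conc[e]) ++cgain; }
        }
        const int64_t s2 = s + (int64_t)d * pow3[v];
        const double v2 = val[s] + gain;
        const int32_t c2 = cc[s] + cgain;
        const int16_t f2 = fw[s] + (yv ? 1 : 0);
        if (v2 > val[s2] ||
            (v2 == val[s2] && (c2 > cc[s2] || (c2 == cc[s2] && f2 > fw[s2])))) {
          val[s2] = v2; cc[s2] = c2; fw[s2] = f2;
        }
      }
    }
  }

  if (bestS < 0) stop("internal error: no complete placement found");

  // backtrack the placement sequence (last placed has highest rank)
  IntegerVector rank(n);
  LogicalVector forward(n);
  int64_t s = bestS;
  for (int p = n; p >= 1; --p) {
    int64_t t = s;
    for (int i = 0; i < n; ++i) { digit[i] = t % 3; t /= 3; }
    bool found = false;
    for (int v = 0; v < n && !found; ++v) {
      const int d = digit[v];
      if (d == 0) continue;
      const int64_t s0 = s - (int64_t)d * pow3[v];
      if (val[s0] < 0) continue;
      const bool yv = (d == 1);
      double gain = 0.0; int32_t cgain = 0;
      for (int k = 0; k < (int)inc[v].size(); ++k) {
        const int e = inc[v][k];
        const int u = (ea[e] == v) ? eb[e] : ea[e];
        const int du = digit[u];
        if (du != 0) {
          // u was placed before v (digits of s0 other than v are unchanged)
          const bool yu = (du == 1);
          const bool fu = f_val(ea[e] == v ? (bool)head_b[e] : (bool)head_a[e], yu);
          const bool fv = f_val(ea[e] == v ? (bool)head_a[e] : (bool)head_b[e], yv);
          if (!fu && fv) { gain += w[e]; if (conc[e]) ++cgain; }
        }
      }
      if (std::abs(val[s0] + gain - val[s]) < 1e-9 &&
          cc[s0] + cgain == cc[s] && fw[s0] + (yv ? 1 : 0) == fw[s]) {
        rank[v] = p;
        forward[v] = yv;
        s = s0;
        found = true;
      }
    }
    if (!found) stop("internal error: DP backtrack failed");
  }

  return List::create(_["rank"] = rank, _["forward"] = forward,
                      _["objective"] = bestV, _["tie_concordant"] = bestC,
                      _["tie_forward"] = (int)bestF);
}
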