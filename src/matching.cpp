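#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

// Maximum-cardinality, cost-minimizing bipartite matching by successive
// shortest augmenting paths with dual potentials (Jonker-Volgenant style).
// cost(i, j) is the edge cost of pairing left vertex i with right vertex j,
// or +Inf if the pair is incompatible. Rows are processed in order; a row
// with no augmenting path is left unmatched (by Berge's lemma it can never
// be matched later, so the final matching has maximum cardinality).
// Returns 1-based column assignment per row, 0 = unmatched.
// [[Rcpp::export]]
IntegerVector ssp_match(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  IntegerVector assign(n, 0);
  if (n == 0 || m == 0) return assign;

  // p[j]: row matched to column j (1-based; 0 = free). Column 0 is the
  // classical sentinel holding the row currently seeking a match.
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    bool reachable = true;
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double c = cost(i0 - 1, j - 1);
        if (std::isfinite(c)) {
          const double cur = c - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      if (!std::isfinite(delta)) {  // no augmenting path: leave i unmatched
        reachable = false;
        break;
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    if (!reachable) continue;
    do {  // augment along the alternating tree
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  for (int j = 1; j <= m; ++j) {
    if (p[j] > 0) assign[p[j] - 1] = j;
  }
  return assign;
}
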