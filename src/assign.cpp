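// Dense linear sum assignment (Jonker-Volgenant shortest augmenting path).
// Used for frame-to-frame trace linking and distance-based detection
// matching; no assignment solver is shipped with the R stack in use.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// cost: n_rows x n_cols, n_rows <= n_cols required (caller pads/transposes).
// Returns 1-based column index assigned to each row. Entries with
// non-finite cost are treated as forbidden; if a row can only be matched
// through a forbidden edge its assignment is reported as NA.
// [[Rcpp::export]]
IntegerVector cpp_lsap(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  const double BIG = 1e30;  // stand-in for forbidden edges, filtered afterwards

  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double c = cost(i0 - 1, j - 1);
        if (!R_finite(c)) c = BIG;
        double cur = c - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector ans(n, NA_INTEGER);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) {
      double c = cost(p[j] - 1, j - 1);
      if (R_finite(c)) ans[p[j] - 1] = j;
    }
  return ans;
}
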