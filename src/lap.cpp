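#include <Rcpp.h>
using namespace Rcpp;

// Exact linear assignment by shortest augmenting paths with potentials
// (Jonker-Volgenant style, O(n^3)). Forbidden entries are +Inf in R and are
// mapped to a large finite cost; feasibility is checked in the R wrapper by
// comparing the solution cost against the forbidden level. Ties are resolved
// deterministically by scanning columns in increasing index order.
// [[Rcpp::export(name = ".lap_cpp")]]
List lap_cpp(NumericMatrix cost, double big) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  auto a = [&](int i, int j) {  // 1-based
    double c = cost(i - 1, j - 1);
    return std::isfinite(c) ? c : big;
  };
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a(i0, j) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector match(n);  // match[i] = column assigned to row i (1-based)
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    match[p[j] - 1] = j;
    total += a(p[j], j);
  }
  return List::create(_["assignment"] = match, _["cost"] = total);
}
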