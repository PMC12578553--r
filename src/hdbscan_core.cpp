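#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum spanning tree of the complete mutual-reachability graph
// d_mreach(i, j) = max(core_i, core_j, d(i, j)), by Prim's algorithm in
// O(n^2) time and O(n) memory (distances computed on the fly; no n x n
// matrix is ever materialised). Returns 1-based endpoints.
// [[Rcpp::export]]
DataFrame cpp_mreach_mst(const NumericMatrix& X, const NumericVector& core_dist) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least two points");
  std::vector<double> P((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) P[(size_t)i * d + c] = X(i, c);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, -1);
  std::vector<bool> used(n, false);
  IntegerVector e_from(n - 1), e_to(n - 1);
  NumericVector e_dist(n - 1);

  int cur = 0;
  used[0] = true;
  for (int it = 0; it < n - 1; ++it) {
    const double* pc = &P[(size_t)cur * d];
    const double cc = core_dist[cur];
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      const double* pj = &P[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = pc[c] - pj[c];
        s += t * t;
      }
      double m = std::sqrt(s);
      if (cc > m) m = cc;
      if (core_dist[j] > m) m = core_dist[j];
      if (m < best[j]) {
        best[j] = m;
        from[j] = cur;
      }
    }
    int nxt = -1;
    double bd = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (!used[j] && best[j] < bd) {
        bd = best[j];
        nxt = j;
      }
    e_from[it] = from[nxt] + 1;
    e_to[it] = nxt + 1;
    e_dist[it] = bd;
    used[nxt] = true;
    cur = nxt;
  }
  return DataFrame::create(_["from"] = e_from, _["to"] = e_to, _["dist"] = e_dist);
}
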