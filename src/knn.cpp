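#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact k-nearest-neighbour search by brute force (Euclidean).
// Rows of X are points. Self is excluded. Neighbours are returned sorted by
// increasing distance; indices are 1-based for R.
// [[Rcpp::export]]
List cpp_knn(const NumericMatrix& X, const int k) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1) stop("k must be at least 1");
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  // row-major copy for cache-friendly inner loops
  std::vector<double> P((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) P[(size_t)i * d + c] = X(i, c);
  std::vector<std::pair<double, int> > heap;
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    const double* pi = &P[(size_t)i * d];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double* pj = &P[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = pi[c] - pj[c];
        s += t * t;
      }
      if ((int)heap.size() < k) {
        heap.push_back(std::make_pair(s, j));
        std::push_heap(heap.begin(), heap.end());
      } else if (s < heap.front().first) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = std::make_pair(s, j);
        std::push_heap(heap.begin(), heap.end());
      }
    }
    std::sort_heap(heap.begin(), heap.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = heap[m].second + 1;
      dist(i, m) = std::sqrt(heap[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
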