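#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clip4(double v) {
  return v > 4.0 ? 4.0 : (v < -4.0 ? -4.0 : v);
}

// Small deterministic RNG so the layout is reproducible for a given seed and
// independent of R's RNG state. xorshift64*.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int bounded(int n) { return (int)(next() % (uint64_t)n); }
};

// Stochastic gradient optimisation of the low-dimensional layout under the
// fuzzy simplicial-set cross-entropy, with negative sampling — the standard
// UMAP layout step. head/tail are 0-based edge endpoints; epochs_per_sample
// follows the reference scheme (max weight sampled every epoch).
// [[Rcpp::export]]
NumericMatrix cpp_umap_optimize(const NumericMatrix& embedding,
                                const IntegerVector& head,
                                const IntegerVector& tail,
                                const NumericVector& epochs_per_sample,
                                const double a, const double b,
                                const double gamma,
                                const int n_epochs,
                                const int negative_rate,
                                const double initial_alpha,
                                const int seed,
                                const bool move_other) {
  const int n_edges = head.size();
  const int n = embedding.nrow();
  const int dim = embedding.ncol();
  // row-major working copy: coordinates of one point are contiguous
  std::vector<double> E((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < dim; ++c) E[(size_t)i * dim + c] = embedding(i, c);
  std::vector<double> next_sample(epochs_per_sample.begin(), epochs_per_sample.end());
  std::vector<double> eps_neg(n_edges), next_neg(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    eps_neg[e] = epochs_per_sample[e] / negative_rate;
    next_neg[e] = eps_neg[e];
  }
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double alpha = initial_alpha * (1.0 - (double)(epoch - 1) / n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (next_sample[e] > epoch) continue;
      double* pi = &E[(size_t)head[e] * dim];
      double* pj = &E[(size_t)tail[e] * dim];

      double d2 = 0.0;
      for (int c = 0; c < dim; ++c) {
        const double t = pi[c] - pj[c];
        d2 += t * t;
      }
      if (d2 > 0.0) {
        const double pd2b = std::pow(d2, b);
        const double coef = (-2.0 * a * b * pd2b / d2) / (a * pd2b + 1.0);
        for (int c = 0; c < dim; ++c) {
          const double g = clip4(coef * (pi[c] - pj[c]));
          pi[c] += alpha * g;
          if (move_other) pj[c] -= alpha * g;
        }
      }
      next_sample[e] += epochs_per_sample[e];

      const int n_neg = (int)((epoch - next_neg[e]) / eps_neg[e]);
      for (int p = 0; p < n_neg; ++p) {
        const int t = rng.bounded(n);
        if (t == head[e]) continue;
        const double* pt = &E[(size_t)t * dim];
        double d2n = 0.0;
        for (int c = 0; c < dim; ++c) {
          const double u = pi[c] - pt[c];
          d2n += u * u;
        }
        if (d2n > 0.0) {
          const double pd2b = std::pow(d2n, b);
          const double coef = (2.0 * gamma * b) / ((0.001 + d2n) * (a * pd2b + 1.0));
          for (int c = 0; c < dim; ++c)
            pi[c] += alpha * clip4(coef * (pi[c] - pt[c]));
        } else {
          // coincident points: push apart by the clipped maximum step
          for (int c = 0; c < dim; ++c) pi[c] += alpha * 4.0;
        }
      }
      next_neg[e] += n_neg * eps_neg[e];
    }
  }
  NumericMatrix out(n, dim);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < dim; ++c) out(i, c) = E[(size_t)i * dim + c];
  return out;
}
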