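// Skip-gram with negative sampling over random-walk corpora.
// Single-threaded and fully deterministic: all randomness comes from an
// internal xorshift generator seeded from R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = "sgns_train")]]
NumericMatrix sgns_train(List walks, int n_nodes, int dim, int window,
                         int negatives, int epochs, double alpha, int seed) {
  if (dim < 1) stop("dim must be >= 1");
  if (epochs < 1) stop("epochs must be >= 1");
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> freq(n_nodes, 0.0);
  long long total_tokens = 0;
  const int n_walks = walks.size();
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector w = walks[wi];
    total_tokens += w.size();
    for (int j = 0; j < w.size(); ++j) {
      int v = w[j] - 1;
      if (v < 0 || v >= n_nodes) stop("walk index out of range");
      freq[v] += 1.0;
    }
  }
  std::vector<double> cdf(n_nodes, 0.0);
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    acc += std::pow(freq[v], 0.75);
    cdf[v] = acc;
  }
  if (acc <= 0) stop("empty walk corpus");
  for (int v = 0; v < n_nodes; ++v) cdf[v] /= acc;

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (rng.unif() - 0.5) / dim;
  }

  const double min_alpha = 1e-4;
  const double total_work =
      static_cast<double>(total_tokens) * epochs;
  long long seen = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      IntegerVector walk = walks[wi];
      const int len = walk.size();
      for (int i = 0; i < len; ++i) {
        ++seen;
        double lr = alpha * (1.0 - static_cast<double>(seen) / (total_work + 1.0));
        if (lr < min_alpha) lr = min_alpha;
        const int center = walk[i] - 1;
        const int b = rng.below(window);  // dynamic window shrink
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= len) continue;
          const int context = walk[j] - 1;
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negatives; ++neg) {
            int tgt;
            double label;
            if (neg == 0) {
              tgt = context;
              label = 1.0;
            } else {
              double u = rng.unif();
              tgt = static_cast<int>(
                  std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
              if (tgt >= n_nodes) tgt = n_nodes - 1;
              if (tgt == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(tgt) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            const double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v) {
    for (int d = 0; d < dim; ++d) {
      out(v, d) = syn0[static_cast<size_t>(v) * dim + d];
    }
  }
  return out;
}
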