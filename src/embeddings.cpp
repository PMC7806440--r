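#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Self-contained RNG (splitmix64-seeded xorshift128+) so training is
// bit-reproducible given the seed, independent of R's RNG state.
namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    s0 = mix(z += 0x9E3779B97F4A7C15ULL);
    s1 = mix(z += 0x9E3779B97F4A7C15ULL);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  static uint64_t mix(uint64_t z) {
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint32_t bounded(uint32_t n) { return (uint32_t)(next() % n); }
};

inline double sigmoid_clip(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// One (input vector, target word) update with negative sampling against the
// shared output layer. `upd_out` is false when the output layer is frozen
// (doc-vector inference phase of the non-joint mode).
inline void train_pair(double* vin, std::vector<double>& out, int target,
                       int k, int ns, double lr,
                       const std::vector<double>& cum, Rng& rng,
                       std::vector<double>& grad, bool upd_out) {
  std::fill(grad.begin(), grad.end(), 0.0);
  double total = cum.back();
  for (int s = 0; s <= ns; ++s) {
    int tgt;
    double label;
    if (s == 0) {
      tgt = target;
      label = 1.0;
    } else {
      double u = rng.unif() * total;
      tgt = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (tgt >= (int)cum.size()) tgt = (int)cum.size() - 1;
      if (tgt == target) continue;
      label = 0.0;
    }
    double* vout = &out[(size_t)tgt * k];
    double f = 0.0;
    for (int j = 0; j < k; ++j) f += vin[j] * vout[j];
    double g = (label - sigmoid_clip(f)) * lr;
    for (int j = 0; j < k; ++j) grad[j] += g * vout[j];
    if (upd_out)
      for (int j = 0; j < k; ++j) vout[j] += g * vin[j];
  }
  for (int j = 0; j < k; ++j) vin[j] += grad[j];
}

} // namespace

// Trains word vectors (skip-gram with negative sampling) and document
// vectors (PV-DBOW) against a shared output layer. docs: list of 1-based
// vocabulary index vectors (out-of-vocabulary tokens already removed).
// freq: corpus frequency of each vocabulary word (negative-sampling table
// uses freq^0.75). joint = true trains D and W simultaneously; false
// pretrains W then fits D against the frozen output layer.
// [[Rcpp::export]]
List cpp_train_embeddings(List docs, NumericVector freq, int k, int ns,
                          int epochs, int window, double alpha,
                          double min_alpha, double seed, bool joint) {
  const int m = docs.size();
  const int n = freq.size();
  std::vector<std::vector<int>> dv(m);
  long long total_tokens = 0;
  for (int d = 0; d < m; ++d) {
    IntegerVector x = docs[d];
    dv[d].resize(x.size());
    for (int t = 0; t < x.size(); ++t) dv[d][t] = x[t] - 1;
    total_tokens += x.size();
  }
  if (total_tokens == 0) stop("no tokens to train on");

  std::vector<double> cum(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += std::pow(freq[i], 0.75);
    cum[i] = acc;
  }

  Rng rng((uint64_t)seed);
  std::vector<double> W((size_t)n * k), D((size_t)m * k),
      Wout((size_t)n * k, 0.0), grad(k);
  for (size_t i = 0; i < W.size(); ++i) W[i] = (rng.unif() - 0.5) / k;
  for (size_t i = 0; i < D.size(); ++i) D[i] = (rng.unif() - 0.5) / k;

  const double span = alpha - min_alpha;
  // phases: joint -> one pass doing both; otherwise skip-gram first, then
  // doc vectors against the frozen output layer
  int n_phases = joint ? 1 : 2;
  for (int phase = 0; phase < n_phases; ++phase) {
    bool do_sg = joint || phase == 0;
    bool do_dbow = joint || phase == 1;
    long long total_pos = total_tokens * (long long)epochs;
    long long processed = 0;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int d = 0; d < m; ++d) {
        const std::vector<int>& toks = dv[d];
        const int T = (int)toks.size();
        for (int t = 0; t < T; ++t) {
          double lr = alpha - span * ((double)processed / (double)total_pos);
          ++processed;
          int w = toks[t];
          if (do_sg) {
            int b = 1 + (int)rng.bounded((uint32_t)window);
            int lo = std::max(0, t - b), hi = std::min(T - 1, t + b);
            for (int j = lo; j <= hi; ++j) {
              if (j == t) continue;
              train_pair(&W[(size_t)w * k], Wout, toks[j], k, ns, lr, cum,
                         rng, grad, true);
            }
          }
          if (do_dbow)
            train_pair(&D[(size_t)d * k], Wout, w, k, ns, lr, cum, rng, grad,
                       joint);
        }
      }
    }
  }

  NumericMatrix Wm(n, k), Dm(m, k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) Wm(i, j) = W[(size_t)i * k + j];
  for (int i = 0; i < m; ++i) {
    bool empty = dv[i].empty();
    for (int j = 0; j < k; ++j) Dm(i, j) = empty ? 0.0 : D[(size_t)i * k + j];
  }
  return List::create(_["W"] = Wm, _["D"] = Dm);
}
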