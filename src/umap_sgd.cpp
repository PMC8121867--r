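// Negative-sampling SGD layout step of UMAP. Edges are the symmetrized
// fuzzy simplicial set (built in R); each edge is sampled in proportion to
// its membership weight via the epochs-per-sample schedule. Deterministic
// given the seed (own xorshift32 stream, single-threaded).
#include <Rcpp.h>
using namespace Rcpp;

static inline uint32_t xorshift32(uint32_t& s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// [[Rcpp::export]]
NumericMatrix umap_sgd_cpp(NumericMatrix emb0, IntegerVector ei,
                           IntegerVector ej, NumericVector ew, int n_epochs,
                           double a, double b, double lr0, int n_neg,
                           int seed) {
  const int n = emb0.nrow(), m = ei.size();
  NumericMatrix emb = clone(emb0);
  std::vector<double> eps(m), next(m);
  const double wmax = max(ew);
  for (int e = 0; e < m; ++e) {
    eps[e] = wmax / ew[e];
    next[e] = eps[e];
  }
  uint32_t rng = (uint32_t)seed;
  if (rng == 0) rng = 42u;
  const double clip = 4.0;
  auto clipv = [&](double v) { return v > clip ? clip : (v < -clip ? -clip : v); };
  for (int ep = 1; ep <= n_epochs; ++ep) {
    const double alpha = lr0 * (1.0 - (double)ep / n_epochs);
    for (int e = 0; e < m; ++e) {
      if (next[e] > ep) continue;
      const int i = ei[e], j = ej[e];
      double dx = emb(i, 0) - emb(j, 0), dy = emb(i, 1) - emb(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0) {
        double gc = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
                    (1.0 + a * std::pow(d2, b));
        double gx = clipv(gc * dx), gy = clipv(gc * dy);
        emb(i, 0) += alpha * gx; emb(i, 1) += alpha * gy;
        emb(j, 0) -= alpha * gx; emb(j, 1) -= alpha * gy;
      }
      for (int t = 0; t < n_neg; ++t) {
        const int kidx = (int)(xorshift32(rng) % (uint32_t)n);
        if (kidx == i) continue;
        double ddx = emb(i, 0) - emb(kidx, 0), ddy = emb(i, 1) - emb(kidx, 1);
        double dd2 = ddx * ddx + ddy * ddy;
        double gc = (2.0 * b) / ((0.001 + dd2) * (1.0 + a * std::pow(dd2, b)));
        emb(i, 0) += alpha * clipv(gc * ddx);
        emb(i, 1) += alpha * clipv(gc * ddy);
      }
      next[e] += eps[e];
    }
  }
  return emb;
}
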