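// Pixel-space primitives with pinned conventions:
// - bilinear resize maps output pixel centers to input coordinates via
//   src = (i + 0.5) * in/out - 0.5 (half-pixel alignment), clamped at the
//   borders;
// - Gaussian blur is separable, kernel truncated at radius ceil(4*sigma),
//   normalized to sum 1, replicate padding at the edges.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector X, int outH, int outW) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 3) stop("expected an H x W x C array");
  const int H = d[0], W = d[1], C = d[2];
  if (outH < 1 || outW < 1) stop("output size must be positive");
  NumericVector out((R_xlen_t)outH * outW * C);
  out.attr("dim") = IntegerVector::create(outH, outW, C);
  std::vector<int> i0(outH), i1(outH); std::vector<double> fi(outH);
  std::vector<int> j0(outW), j1(outW); std::vector<double> fj(outW);
  for (int i = 0; i < outH; ++i) {
    double s = (i + 0.5) * (double)H / outH - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s); i1[i] = std::min(i0[i] + 1, H - 1); fi[i] = s - i0[i];
  }
  for (int j = 0; j < outW; ++j) {
    double s = (j + 0.5) * (double)W / outW - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s); j1[j] = std::min(j0[j] + 1, W - 1); fj[j] = s - j0[j];
  }
  for (int c = 0; c < C; ++c) {
    const double* src = X.begin() + (R_xlen_t)c * H * W;
    double* dst = out.begin() + (R_xlen_t)c * outH * outW;
    for (int j = 0; j < outW; ++j) {
      for (int i = 0; i < outH; ++i) {
        double v00 = src[i0[i] + j0[j] * H], v10 = src[i1[i] + j0[j] * H];
        double v01 = src[i0[i] + j1[j] * H], v11 = src[i1[i] + j1[j] * H];
        double v0 = v00 + (v10 - v00) * fi[i];
        double v1 = v01 + (v11 - v01) * fi[i];
        dst[i + j * outH] = v0 + (v1 - v0) * fj[j];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gauss_blur_cpp(NumericVector X, double sigma) {
  IntegerVector d = X.attr("dim");
  if (d.size() != 3) stop("expected an H x W x C array");
  if (sigma <= 0) stop("sigma must be > 0");
  const int H = d[0], W = d[1], C = d[2];
  const int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  NumericVector out(X.size());
  out.attr("dim") = d;
  std::vector<double> tmp((size_t)H * W);
  for (int c = 0; c < C; ++c) {
    const double* src = X.begin() + (R_xlen_t)c * H * W;
    double* dst = out.begin() + (R_xlen_t)c * H * W;
    // vertical pass (rows), replicate padding
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int ii = i + t;
          if (ii < 0) ii = 0; if (ii > H - 1) ii = H - 1;
          acc += k[t + r] * src[ii + j * H];
        }
        tmp[i + (size_t)j * H] = acc;
      }
    // horizontal pass
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int jj = j + t;
          if (jj < 0) jj = 0; if (jj > W - 1) jj = W - 1;
          acc += k[t + r] * tmp[i + (size_t)jj * H];
        }
        dst[i + j * H] = acc;
      }
  }
  return out;
}
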