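// Compact CNN engine: four stride-2 valid convolutions -> ReLU -> global
// max-pool -> three ReLU fully-connected layers -> 3-class softmax.
// Feature maps are stored as (channels x H*W) matrices, spatial index
// p = i + j*H (column-major, matching R arrays). Convolution is im2col +
// GEMM. Backward passes return weight gradients and, where requested,
// gradients with respect to the input pixels (needed for integrated
// gradients).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct Net {
  int k, stride;
  std::vector<mat> CW; std::vector<vec> CB;   // conv: (cout x cin*k*k)
  std::vector<mat> FW; std::vector<vec> FB;   // fc hidden: (out x in)
  mat OW; vec OB;                             // classification layer (3 x fc_last)
};

static Net parse_net(const List& wts) {
  Net n;
  List cfg = wts["config"];
  n.k = as<int>(cfg["conv_kernel"]);
  n.stride = as<int>(cfg["conv_stride"]);
  List cw = wts["cw"], cb = wts["cb"], fw = wts["fw"], fb = wts["fb"];
  for (int l = 0; l < cw.size(); ++l) {
    n.CW.push_back(as<mat>(cw[l]));
    n.CB.push_back(as<vec>(cb[l]));
  }
  for (int l = 0; l < fw.size(); ++l) {
    n.FW.push_back(as<mat>(fw[l]));
    n.FB.push_back(as<vec>(fb[l]));
  }
  n.OW = as<mat>(wts["ow"]);
  n.OB = as<vec>(wts["ob"]);
  return n;
}

// cols(r, p_out) with r = c + C*(ki + kj*k)
static mat im2col(const mat& F, int H, int W, int k, int s, int& Ho, int& Wo) {
  const int C = F.n_rows;
  Ho = (H - k) / s + 1;
  Wo = (W - k) / s + 1;
  mat out(C * k * k, Ho * Wo);
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      double* dst = out.colptr(oi + oj * Ho);
      const int bi = oi * s, bj = oj * s;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double* src = F.colptr((bi + ki) + (bj + kj) * H);
          double* d = dst + (ki + kj * k) * C;
          std::copy(src, src + C, d);
        }
      }
    }
  }
  return out;
}

static void col2im_add(mat& dF, const mat& dcols, int H, int W, int k, int s,
                       int Ho, int Wo) {
  const int C = dF.n_rows;
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const double* src = dcols.colptr(oi + oj * Ho);
      const int bi = oi * s, bj = oj * s;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          double* dst = dF.colptr((bi + ki) + (bj + kj) * H);
          const double* s2 = src + (ki + kj * k) * C;
          for (int c = 0; c < C; ++c) dst[c] += s2[c];
        }
      }
    }
  }
}

struct Cache {
  std::vector<mat> cin;    // conv layer inputs
  std::vector<mat> cols;   // im2col of each conv input
  std::vector<mat> cout_;  // conv outputs post-ReLU
  std::vector<int> Hs, Ws; // input spatial dims per conv layer
  uvec maxidx;
  vec pooled;
  std::vector<vec> fca;    // fc activations post-ReLU
  vec probs;
};

static void forward_one(const Net& net, const mat& X0, int H, int W, Cache& c,
                        bool keep) {
  mat F = X0;
  int h = H, w = W;
  const int nconv = net.CW.size();
  for (int l = 0; l < nconv; ++l) {
    if (h < net.k || w < net.k)
      stop("input too small for conv layer %d (spatial %dx%d, kernel %d)",
           l + 1, h, w, net.k);
    int Ho, Wo;
    mat cols = im2col(F, h, w, net.k, net.stride, Ho, Wo);
    mat out = net.CW[l] * cols;
    out.each_col() += net.CB[l];
    out.elem(arma::find(out < 0)).zeros();
    if (keep) {
      c.cin.push_back(F); c.cols.push_back(cols); c.cout_.push_back(out);
      c.Hs.push_back(h); c.Ws.push_back(w);
    }
    F = out; h = Ho; w = Wo;
  }
  // global max pool over spatial positions
  const int C = F.n_rows;
  vec pooled(C); uvec idx(C);
  for (int r = 0; r < C; ++r) {
    arma::rowvec row = F.row(r);
    idx(r) = row.index_max();
    pooled(r) = row(idx(r));
  }
  c.maxidx = idx; c.pooled = pooled;
  if (!keep) { c.cout_.clear(); c.cout_.push_back(F); }
  vec a = pooled;
  c.fca.clear();
  for (size_t l = 0; l < net.FW.size(); ++l) {
    vec z = net.FW[l] * a + net.FB[l];
    z.elem(arma::find(z < 0)).zeros();
    c.fca.push_back(z);
    a = z;
  }
  vec logits = net.OW * a + net.OB;
  logits -= logits.max();
  vec e = arma::exp(logits);
  c.probs = e / arma::accu(e);
}

struct Grads {
  std::vector<mat> dCW; std::vector<vec> dCB;
  std::vector<mat> dFW; std::vector<vec> dFB;
  mat dOW; vec dOB;
  void init(const Net& n) {
    for (auto& m : n.CW) dCW.push_back(mat(m.n_rows, m.n_cols, arma::fill::zeros));
    for (auto& v : n.CB) dCB.push_back(vec(v.n_elem, arma::fill::zeros));
    for (auto& m : n.FW) dFW.push_back(mat(m.n_rows, m.n_cols, arma::fill::zeros));
    for (auto& v : n.FB) dFB.push_back(vec(v.n_elem, arma::fill::zeros));
    dOW = mat(n.OW.n_rows, n.OW.n_cols, arma::fill::zeros);
    dOB = vec(n.OB.n_elem, arma::fill::zeros);
  }
  List as_list(const List& wts) const {
    List cw(dCW.size()), cb(dCB.size()), fw(dFW.size()), fb(dFB.size());
    for (size_t l = 0; l < dCW.size(); ++l) { cw[l] = wrap(dCW[l]); cb[l] = wrap(dCB[l]); }
    for (size_t l = 0; l < dFW.size(); ++l) { fw[l] = wrap(dFW[l]); fb[l] = wrap(dFB[l]); }
    return List::create(_["cw"] = cw, _["cb"] = cb, _["fw"] = fw, _["fb"] = fb,
                        _["ow"] = wrap(dOW), _["ob"] = wrap(dOB),
                        _["config"] = wts["config"]);
  }
};

// dlogits -> weight grads (+ optional input grad)
static void backward_one(const Net& net, const Cache& c, const vec& dlogits,
                         Grads& g, mat* dX) {
  const int nfc = net.FW.size();
  g.dOW += dlogits * c.fca[nfc - 1].t();
  g.dOB += dlogits;
  vec da = net.OW.t() * dlogits;
  for (int l = nfc - 1; l >= 0; --l) {
    vec dz = da;
    for (arma::uword i = 0; i < dz.n_elem; ++i)
      if (c.fca[l](i) <= 0) dz(i) = 0;
    const vec& prev = (l == 0) ? c.pooled : c.fca[l - 1];
    g.dFW[l] += dz * prev.t();
    g.dFB[l] += dz;
    da = net.FW[l].t() * dz;
  }
  const int nconv = net.CW.size();
  const mat& last = c.cout_[nconv - 1];
  mat dF(last.n_rows, last.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < last.n_rows; ++r) dF(r, c.maxidx(r)) += da(r);
  for (int l = nconv - 1; l >= 0; --l) {
    mat dpre = dF;
    const mat& out = c.cout_[l];
    for (arma::uword i = 0; i < dpre.n_elem; ++i)
      if (out(i) <= 0) dpre(i) = 0;
    g.dCW[l] += dpre * c.cols[l].t();
    g.dCB[l] += arma::sum(dpre, 1);
    mat dcols = net.CW[l].t() * dpre;
    const int H = c.Hs[l], W = c.Ws[l];
    mat dFin(c.cin[l].n_rows, H * W, arma::fill::zeros);
    const int Ho = (H - net.k) / net.stride + 1;
    const int Wo = (W - net.k) / net.stride + 1;
    col2im_add(dFin, dcols, H, W, net.k, net.stride, Ho, Wo);
    dF = dFin;
  }
  if (dX) *dX = dF;
}

static void get_dims(const NumericVector& X, int& H, int& W, int& C, int& N) {
  IntegerVector d = X.attr("dim");
  if (d.size() == 3) { H = d[0]; W = d[1]; C = d[2]; N = 1; }
  else if (d.size() == 4) { H = d[0]; W = d[1]; C = d[2]; N = d[3]; }
  else stop("expected a H x W x C (x N) array");
  if (C != 3) stop("expected 3 channels, got %d", C);
}

// image n as (C x H*W) matrix
static mat slice_img(const NumericVector& X, int H, int W, int C, int n) {
  mat F(C, H * W);
  const double* base = X.begin() + (R_xlen_t)n * H * W * C;
  for (int c = 0; c < C; ++c) {
    const double* src = base + (R_xlen_t)c * H * W;
    for (int p = 0; p < H * W; ++p) F(c, p) = src[p];
  }
  return F;
}

// [[Rcpp::export]]
List cnn_forward_cpp(List wts, NumericVector X, bool hidden = false) {
  Net net = parse_net(wts);
  int H, W, C, N; get_dims(X, H, W, C, N);
  NumericMatrix probs(N, 3);
  int hdim = 0;
  for (auto& fw : net.FW) hdim += fw.n_rows;
  hdim += 3;
  NumericMatrix hid(hidden ? N : 0, hidden ? hdim : 0);
  for (int n = 0; n < N; ++n) {
    Cache c;
    forward_one(net, slice_img(X, H, W, C, n), H, W, c, false);
    for (int j = 0; j < 3; ++j) probs(n, j) = c.probs(j);
    if (hidden) {
      int off = 0;
      for (auto& a : c.fca)
        for (arma::uword i = 0; i < a.n_elem; ++i) hid(n, off++) = a(i);
      for (int j = 0; j < 3; ++j) hid(n, off++) = c.probs(j);
    }
  }
  if (hidden) return List::create(_["probs"] = probs, _["hidden"] = hid);
  return List::create(_["probs"] = probs);
}

// mean cross-entropy over the batch; y in {0,1,2}
// [[Rcpp::export]]
List cnn_cell_grad_cpp(List wts, NumericVector X, IntegerVector y) {
  Net net = parse_net(wts);
  int H, W, C, N; get_dims(X, H, W, C, N);
  if (y.size() != N) stop("length(y) must equal number of images");
  Grads g; g.init(net);
  NumericMatrix probs(N, 3);
  double loss = 0;
  for (int n = 0; n < N; ++n) {
    Cache c;
    forward_one(net, slice_img(X, H, W, C, n), H, W, c, true);
    for (int j = 0; j < 3; ++j) probs(n, j) = c.probs(j);
    const int cls = y[n];
    if (cls < 0 || cls > 2) stop("labels must be 0, 1 or 2");
    loss += -std::log(std::max(c.probs(cls), 1e-12));
    vec dlogits = c.probs;
    dlogits(cls) -= 1.0;
    dlogits /= (double)N;
    backward_one(net, c, dlogits, g, nullptr);
  }
  return List::create(_["loss"] = loss / N, _["probs"] = probs,
                      _["grads"] = g.as_list(wts));
}

// multiple-instance bag: loss = CE(mean_i softmax_i, ybag)
// [[Rcpp::export]]
List cnn_bag_grad_cpp(List wts, NumericVector X, int ybag) {
  Net net = parse_net(wts);
  int H, W, C, N; get_dims(X, H, W, C, N);
  if (ybag < 0 || ybag > 2) stop("bag label must be 0, 1 or 2");
  Grads g; g.init(net);
  std::vector<Cache> caches(N);
  vec bagp(3, arma::fill::zeros);
  NumericMatrix probs(N, 3);
  for (int n = 0; n < N; ++n) {
    forward_one(net, slice_img(X, H, W, C, n), H, W, caches[n], true);
    bagp += caches[n].probs;
    for (int j = 0; j < 3; ++j) probs(n, j) = caches[n].probs(j);
  }
  bagp /= (double)N;
  double loss = -std::log(std::max(bagp(ybag), 1e-12));
  vec gbag(3, arma::fill::zeros);
  gbag(ybag) = -1.0 / std::max(bagp(ybag), 1e-12);
  for (int n = 0; n < N; ++n) {
    const vec& p = caches[n].probs;
    // d(mean CE)/dlogits_n = (1/N) * J_softmax(p)^T gbag
    vec dlogits = (p % gbag - p * arma::dot(p, gbag)) / (double)N;
    backward_one(net, caches[n], dlogits, g, nullptr);
  }
  return List::create(_["loss"] = loss, _["bag_probs"] = wrap(bagp),
                      _["probs"] = probs, _["grads"] = g.as_list(wts));
}

// gradient of deltaP = P(APL) - P(non-APL) = p[1] - p[0] w.r.t. pixels
// [[Rcpp::export]]
List cnn_input_grad_cpp(List wts, NumericVector X) {
  Net net = parse_net(wts);
  int H, W, C, N; get_dims(X, H, W, C, N);
  NumericVector grad(X.size());
  grad.attr("dim") = X.attr("dim");
  NumericVector delta(N);
  Grads g; g.init(net);
  vec u = {-1.0, 1.0, 0.0};
  for (int n = 0; n < N; ++n) {
    Cache c;
    forward_one(net, slice_img(X, H, W, C, n), H, W, c, true);
    delta[n] = c.probs(1) - c.probs(0);
    vec dlogits = c.probs % u - c.probs * arma::dot(c.probs, u);
    mat dX;
    backward_one(net, c, dlogits, g, &dX);
    double* base = grad.begin() + (R_xlen_t)n * H * W * C;
    for (int ch = 0; ch < C; ++ch) {
      double* dst = base + (R_xlen_t)ch * H * W;
      for (int p = 0; p < H * W; ++p) dst[p] = dX(ch, p);
    }
  }
  return List::create(_["grad"] = grad, _["delta"] = delta);
}
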