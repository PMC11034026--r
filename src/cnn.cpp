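// Self-contained 2D CNN on 64x64 pattern matrices.
//
// Layer stack: [conv(F, k1 x k2, same, ReLU) -> maxpool(S1, stride S2, same)
// -> dropout(P)] x 2 -> flatten -> dense(R, ReLU) -> dense(C) -> softmax.
// Convolutions are im2col + GEMM, with whole mini-batches stacked into one
// GEMM (rows of image b live at offset b * L * L); the full Adam training
// loop runs here so no per-batch work crosses the R boundary.  Internals
// run in single precision (the GEMMs dominate single-CPU training time);
// softmax/loss and everything returned to R are double.  Dropout uses
// inverted scaling 1/(1-P) at train time so inference needs no rescaling.
// All randomness (shuffling order, dropout seeds) is supplied by the
// caller, keeping runs reproducible from R's RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

struct Dims {
  int L, F, k1, k2, S1, S2, R, C;
  int L1, L2, flat;
};

static Dims read_dims(const List& cfg) {
  Dims d;
  d.L  = as<int>(cfg["L"]);
  d.F  = as<int>(cfg["nFilters"]);
  d.k1 = as<int>(cfg["k1"]);
  d.k2 = as<int>(cfg["k2"]);
  d.S1 = as<int>(cfg["poolSize"]);
  d.S2 = as<int>(cfg["poolStride"]);
  d.R  = as<int>(cfg["denseUnits"]);
  d.C  = as<int>(cfg["nClasses"]);
  d.L1 = (d.L + d.S2 - 1) / d.S2;
  d.L2 = (d.L1 + d.S2 - 1) / d.S2;
  d.flat = d.L2 * d.L2 * d.F;
  return d;
}

// ---- offset-based layer primitives -------------------------------------
// Joined matrices stack images along rows: image b of a C_in-channel
// L x L activation occupies rows [b*L*L, (b+1)*L*L) of an (B*L*L) x C_in
// matrix (pixel index i + j*L within the block, column-major per channel).

// same-padding im2col of one image block into its block of `col`
static void im2col_at(const arma::fmat& X, arma::uword xoff,
                      arma::fmat& col, arma::uword coff,
                      int L, int Cin, int k1, int k2) {
  const int pad1 = (k1 - 1) / 2, pad2 = (k2 - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    const float* xp = X.colptr(c) + xoff;
    for (int n = 0; n < k2; ++n) {
      for (int m = 0; m < k1; ++m) {
        float* cp = col.colptr(c * k1 * k2 + n * k1 + m) + coff;
        const int i0 = std::max(0, pad1 - m);
        const int i1 = std::min(L, L + pad1 - m);
        for (int j = 0; j < L; ++j) {
          const int sj = j + n - pad2;
          if (sj < 0 || sj >= L || i1 <= i0) {
            std::fill(cp + j * L, cp + (j + 1) * L, 0.0f);
            continue;
          }
          std::fill(cp + j * L, cp + j * L + i0, 0.0f);
          std::copy(xp + (i0 + m - pad1) + sj * L,
                    xp + (i1 + m - pad1) + sj * L,
                    cp + i0 + j * L);
          std::fill(cp + i1 + j * L, cp + (j + 1) * L, 0.0f);
        }
      }
    }
  }
}

// adjoint: scatter-add one image block of column gradients onto dX
static void col2im_at(const arma::fmat& dcol, arma::uword coff,
                      arma::fmat& dX, arma::uword xoff,
                      int L, int Cin, int k1, int k2) {
  const int pad1 = (k1 - 1) / 2, pad2 = (k2 - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    float* xp = dX.colptr(c) + xoff;
    for (int n = 0; n < k2; ++n) {
      for (int m = 0; m < k1; ++m) {
        const float* cp = dcol.colptr(c * k1 * k2 + n * k1 + m) + coff;
        const int i0 = std::max(0, pad1 - m);
        const int i1 = std::min(L, L + pad1 - m);
        if (i1 <= i0) continue;
        for (int j = 0; j < L; ++j) {
          const int sj = j + n - pad2;
          if (sj < 0 || sj >= L) continue;
          const float* src = cp + i0 + j * L;
          float* dst = xp + (i0 + m - pad1) + sj * L;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// max over S1 x S1 windows at stride S2, "same" (windows clipped at the
// edge); argmax indices are relative to the image block
static void maxpool_at(const arma::fmat& X, arma::uword xoff,
                       arma::fmat& out, arma::umat& amax, arma::uword ooff,
                       int L, int S1, int S2) {
  const int Lp = (L + S2 - 1) / S2;
  for (arma::uword f = 0; f < X.n_cols; ++f) {
    const float* xp = X.colptr(f) + xoff;
    float* op = out.colptr(f) + ooff;
    arma::uword* ap = amax.colptr(f) + ooff;
    for (int jp = 0; jp < Lp; ++jp) {
      const int j0 = jp * S2, j1 = std::min(j0 + S1, L);
      for (int ip = 0; ip < Lp; ++ip) {
        const int i0 = ip * S2, i1 = std::min(i0 + S1, L);
        float best = xp[i0 + j0 * L];
        int argb = i0 + j0 * L;
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i) {
            const int p = i + j * L;
            if (xp[p] > best) { best = xp[p]; argb = p; }
          }
        op[ip + jp * Lp] = best;
        ap[ip + jp * Lp] = argb;
      }
    }
  }
}

static void unpool_at(const arma::fmat& dP, const arma::umat& amax,
                      arma::uword poff, arma::fmat& dX, arma::uword xoff,
                      int Lp) {
  const arma::uword nP = (arma::uword)Lp * Lp;
  for (arma::uword f = 0; f < dP.n_cols; ++f) {
    const float* dp = dP.colptr(f) + poff;
    const arma::uword* ap = amax.colptr(f) + poff;
    float* xp = dX.colptr(f) + xoff;
    for (arma::uword p = 0; p < nP; ++p) xp[ap[p]] += dp[p];
  }
}

static void relu_(arma::fmat& Z) {
  for (arma::uword i = 0; i < Z.n_elem; ++i) if (Z(i) < 0.0f) Z(i) = 0.0f;
}

static arma::fmat drop_mask(arma::uword nr, arma::uword nc, double P,
                            std::mt19937& rng) {
  arma::fmat m(nr, nc);
  if (P <= 0) { m.ones(); return m; }
  const float scale = (float)(1.0 / (1.0 - P));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (arma::uword i = 0; i < m.n_elem; ++i)
    m(i) = (unif(rng) < P) ? 0.0f : scale;
  return m;
}

// ---- parameters ---------------------------------------------------------

struct Params {
  arma::fmat W1, W2, W3, W4;
  arma::fvec b1, b2, b3, b4;
  std::vector<arma::fmat*> mats() { return {&W1, &W2, &W3, &W4}; }
  std::vector<arma::fvec*> vecs() { return {&b1, &b2, &b3, &b4}; }
};

static arma::fmat as_f(const NumericMatrix& m) {
  arma::fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static arma::fvec as_fv(const NumericVector& v) {
  arma::fvec out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}
static NumericMatrix as_R(const arma::fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static NumericVector as_Rv(const arma::fvec& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

static Params read_params(const List& par, const Dims& d) {
  Params p;
  p.W1 = as_f(par["W1"]); p.b1 = as_fv(par["b1"]);
  p.W2 = as_f(par["W2"]); p.b2 = as_fv(par["b2"]);
  p.W3 = as_f(par["W3"]); p.b3 = as_fv(par["b3"]);
  p.W4 = as_f(par["W4"]); p.b4 = as_fv(par["b4"]);
  if ((int)p.W1.n_rows != d.k1 * d.k2 || (int)p.W1.n_cols != d.F ||
      (int)p.W2.n_rows != d.k1 * d.k2 * d.F ||
      (int)p.W3.n_rows != d.flat || (int)p.W3.n_cols != d.R ||
      (int)p.W4.n_rows != d.R || (int)p.W4.n_cols != d.C)
    stop("parameter shapes do not match the configuration");
  return p;
}

// ---- batched forward / backward ----------------------------------------

struct BatchCache {
  arma::fmat col1, Z1, P1, M1, col2, Z2, P2, M2, Fl, H;
  arma::umat A1, A2;
  arma::mat prob;  // B x C, double
};

// Xb: (B*L*L) x 1 joined single-channel input
static void forward_batch(const arma::fmat& Xb, int B, const Params& p,
                          const Dims& d, bool train, std::mt19937* rng,
                          double Pdrop, BatchCache& cc) {
  const arma::uword n0 = (arma::uword)d.L * d.L;
  const arma::uword n1 = (arma::uword)d.L1 * d.L1;
  const arma::uword n2 = (arma::uword)d.L2 * d.L2;

  cc.col1.set_size(B * n0, d.k1 * d.k2);
  for (int b = 0; b < B; ++b)
    im2col_at(Xb, b * n0, cc.col1, b * n0, d.L, 1, d.k1, d.k2);
  cc.Z1 = cc.col1 * p.W1;
  cc.Z1.each_row() += p.b1.t();
  relu_(cc.Z1);  // Z1 holds the post-ReLU maps; >0 doubles as the mask
  cc.P1.set_size(B * n1, d.F); cc.A1.set_size(B * n1, d.F);
  for (int b = 0; b < B; ++b)
    maxpool_at(cc.Z1, b * n0, cc.P1, cc.A1, b * n1, d.L, d.S1, d.S2);
  arma::fmat D1;
  if (train) { cc.M1 = drop_mask(B * n1, d.F, Pdrop, *rng); D1 = cc.P1 % cc.M1; }
  else D1 = cc.P1;

  cc.col2.set_size(B * n1, d.k1 * d.k2 * d.F);
  for (int b = 0; b < B; ++b)
    im2col_at(D1, b * n1, cc.col2, b * n1, d.L1, d.F, d.k1, d.k2);
  cc.Z2 = cc.col2 * p.W2;
  cc.Z2.each_row() += p.b2.t();
  relu_(cc.Z2);
  cc.P2.set_size(B * n2, d.F); cc.A2.set_size(B * n2, d.F);
  for (int b = 0; b < B; ++b)
    maxpool_at(cc.Z2, b * n1, cc.P2, cc.A2, b * n2, d.L1, d.S1, d.S2);
  arma::fmat D2;
  if (train) { cc.M2 = drop_mask(B * n2, d.F, Pdrop, *rng); D2 = cc.P2 % cc.M2; }
  else D2 = cc.P2;

  // flatten: column b = vectorised (n2 x F) block of image b
  cc.Fl.set_size(d.flat, B);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < d.F; ++f)
      std::copy(D2.colptr(f) + b * n2, D2.colptr(f) + (b + 1) * n2,
                cc.Fl.colptr(b) + (arma::uword)f * n2);
  cc.H = cc.Fl.t() * p.W3;
  cc.H.each_row() += p.b3.t();
  relu_(cc.H);
  arma::fmat logits = cc.H * p.W4;
  logits.each_row() += p.b4.t();

  cc.prob.set_size(B, d.C);
  for (int b = 0; b < B; ++b) {
    arma::rowvec lg = arma::conv_to<arma::rowvec>::from(logits.row(b));
    lg -= lg.max();
    arma::rowvec ex = arma::exp(lg);
    cc.prob.row(b) = ex / arma::accu(ex);
  }
}

struct Grads {
  arma::fmat W1, W2, W3, W4;
  arma::fvec b1, b2, b3, b4;
  void init(const Params& p) {
    W1.zeros(arma::size(p.W1)); W2.zeros(arma::size(p.W2));
    W3.zeros(arma::size(p.W3)); W4.zeros(arma::size(p.W4));
    b1.zeros(p.b1.n_elem); b2.zeros(p.b2.n_elem);
    b3.zeros(p.b3.n_elem); b4.zeros(p.b4.n_elem);
  }
  std::vector<arma::fmat*> mats() { return {&W1, &W2, &W3, &W4}; }
  std::vector<arma::fvec*> vecs() { return {&b1, &b2, &b3, &b4}; }
};

// gradients are averaged over the batch
static void backward_batch(const arma::fmat& Xb, int B,
                           const IntegerVector& yb, const Params& p,
                           const Dims& d, const BatchCache& cc, Grads& g,
                           double& loss, double& acc) {
  const arma::uword n1 = (arma::uword)d.L1 * d.L1;
  const arma::uword n2 = (arma::uword)d.L2 * d.L2;
  const float inv = 1.0f / B;

  loss = 0.0; int ncorrect = 0;
  arma::fmat dlog(B, d.C);
  for (int b = 0; b < B; ++b) {
    const int yy = yb[b];
    loss += -std::log(std::max(cc.prob(b, yy), 1e-12));
    if ((int)cc.prob.row(b).index_max() == yy) ++ncorrect;
    for (int c = 0; c < d.C; ++c)
      dlog(b, c) = (float)cc.prob(b, c) - (c == yy ? 1.0f : 0.0f);
  }
  dlog *= inv;
  loss /= B; acc = (double)ncorrect / B;

  g.W4 = cc.H.t() * dlog;
  g.b4 = arma::sum(dlog, 0).t();
  arma::fmat dH = dlog * p.W4.t();
  for (arma::uword i = 0; i < dH.n_elem; ++i)
    if (cc.H(i) <= 0.0f) dH(i) = 0.0f;
  g.W3 = cc.Fl * dH;
  g.b3 = arma::sum(dH, 0).t();
  arma::fmat dFl = p.W3 * dH.t();  // flat x B

  // un-flatten to joined (B*n2) x F, apply dropout mask
  arma::fmat dD2(B * n2, d.F);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < d.F; ++f)
      std::copy(dFl.colptr(b) + (arma::uword)f * n2,
                dFl.colptr(b) + (arma::uword)(f + 1) * n2,
                dD2.colptr(f) + b * n2);
  if (cc.M2.n_elem) dD2 %= cc.M2;

  arma::fmat dZ2(arma::size(cc.Z2), arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    unpool_at(dD2, cc.A2, b * n2, dZ2, b * n1, d.L2);
  for (arma::uword i = 0; i < dZ2.n_elem; ++i)
    if (cc.Z2(i) <= 0.0f) dZ2(i) = 0.0f;
  g.W2 = cc.col2.t() * dZ2;
  g.b2 = arma::sum(dZ2, 0).t();
  arma::fmat dcol2 = dZ2 * p.W2.t();
  arma::fmat dD1(arma::size(cc.P1), arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    col2im_at(dcol2, b * n1, dD1, b * n1, d.L1, d.F, d.k1, d.k2);
  if (cc.M1.n_elem) dD1 %= cc.M1;

  const arma::uword n0 = (arma::uword)d.L * d.L;
  arma::fmat dZ1(arma::size(cc.Z1), arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    unpool_at(dD1, cc.A1, b * n1, dZ1, b * n0, d.L1);
  for (arma::uword i = 0; i < dZ1.n_elem; ++i)
    if (cc.Z1(i) <= 0.0f) dZ1(i) = 0.0f;
  g.W1 = cc.col1.t() * dZ1;
  g.b1 = arma::sum(dZ1, 0).t();
}

// gather image slices into a joined (B*L*L) x 1 single-channel matrix
static arma::fmat gather(const double* x, const Dims& d,
                         const std::vector<int>& idx) {
  const arma::uword n0 = (arma::uword)d.L * d.L;
  arma::fmat Xb(idx.size() * n0, 1);
  float* out = Xb.colptr(0);
  for (size_t b = 0; b < idx.size(); ++b) {
    const double* src = x + (arma::uword)idx[b] * n0;
    for (arma::uword i = 0; i < n0; ++i) out[b * n0 + i] = (float)src[i];
  }
  return Xb;
}

static arma::mat predict_all(const double* x, int n, const Params& p,
                             const Dims& d, int chunk) {
  arma::mat prob(n, d.C);
  BatchCache cc;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(s + chunk, n);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    arma::fmat Xb = gather(x, d, idx);
    forward_batch(Xb, e - s, p, d, false, nullptr, 0.0, cc);
    prob.rows(s, e - 1) = cc.prob;
  }
  return prob;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(NumericVector x, List params, List cfg) {
  Dims d = read_dims(cfg);
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != d.L || dim[1] != d.L)
    stop("input must be an L x L x n array");
  const int B = dim[2];
  Params p = read_params(params, d);
  NumericMatrix out(B, d.C);
  if (B == 0) return out;
  arma::mat prob = predict_all(x.begin(), B, p, d, 8);
  std::copy(prob.begin(), prob.end(), out.begin());
  return out;
}

// single forward+backward pass over one batch, returning averaged
// gradients (used by the R-level optimiser tests and diagnostics)
// [[Rcpp::export(name = ".cnn_train_batch_cpp")]]
List cnn_train_batch_cpp(NumericVector x, IntegerVector y, List params,
                         List cfg, double dropP, int seed) {
  Dims d = read_dims(cfg);
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != d.L || dim[1] != d.L)
    stop("input must be an L x L x n array");
  const int B = dim[2];
  if (y.size() != B) stop("labels and inputs differ in length");
  for (int b = 0; b < B; ++b)
    if (y[b] < 0 || y[b] >= d.C) stop("label index out of range");
  Params p = read_params(params, d);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(B);
  for (int i = 0; i < B; ++i) idx[i] = i;
  arma::fmat Xb = gather(x.begin(), d, idx);
  BatchCache cc;
  forward_batch(Xb, B, p, d, true, &rng, dropP, cc);
  Grads g;
  double loss, acc;
  backward_batch(Xb, B, y, p, d, cc, g, loss, acc);
  List grads = List::create(
    _["W1"] = as_R(g.W1), _["b1"] = as_Rv(g.b1),
    _["W2"] = as_R(g.W2), _["b2"] = as_Rv(g.b2),
    _["W3"] = as_R(g.W3), _["b3"] = as_Rv(g.b3),
    _["W4"] = as_R(g.W4), _["b4"] = as_Rv(g.b4));
  return List::create(_["loss"] = loss, _["acc"] = acc,
                      _["grads"] = grads);
}

// full training loop: mini-batch Adam over `epochs` passes.
// order: n x epochs matrix of 1-based shuffles; dropSeeds: one dropout
// seed per epoch (both drawn from R's RNG by the caller).  patience > 0
// stops early once validation loss has not improved for that many epochs.
// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(NumericVector x, IntegerVector y, List params, List cfg,
                   double lr, int batchSize, int epochs, double dropP,
                   IntegerMatrix order, IntegerVector dropSeeds,
                   Nullable<NumericVector> valx_,
                   Nullable<IntegerVector> valy_, int patience) {
  Dims d = read_dims(cfg);
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != d.L || dim[1] != d.L)
    stop("input must be an L x L x n array");
  const int n = dim[2];
  if (y.size() != n) stop("labels and inputs differ in length");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= d.C) stop("label index out of range");
  if (order.nrow() != n || order.ncol() < epochs)
    stop("'order' must be n x epochs");
  if (dropSeeds.size() < epochs) stop("need one dropout seed per epoch");
  Params p = read_params(params, d);

  const bool hasVal = valx_.isNotNull();
  NumericVector valx; IntegerVector valy; int nVal = 0;
  if (hasVal) {
    valx = valx_.get(); valy = valy_.get();
    IntegerVector vd = valx.attr("dim");
    nVal = vd[2];
    if (valy.size() != nVal)
      stop("validation labels and inputs differ in length");
  }

  Grads m, v;   // Adam moments
  m.init(p); v.init(p);
  const float beta1 = 0.9f, beta2 = 0.999f, epsA = 1e-8f;
  long step = 0;
  NumericMatrix history(epochs, 4);
  colnames(history) = CharacterVector::create("loss", "acc",
                                              "valLoss", "valAcc");

  if (patience > 0 && !hasVal)
    stop("early stopping requires a validation set");
  double bestVal = std::numeric_limits<double>::infinity();
  int wait = 0, epochsRun = 0;

  BatchCache cc;
  Grads g;
  for (int ep = 0; ep < epochs; ++ep) {
    std::mt19937 rng((unsigned)dropSeeds[ep]);
    double epLoss = 0.0, epAcc = 0.0;
    for (int s = 0; s < n; s += batchSize) {
      const int e = std::min(s + batchSize, n);
      const int B = e - s;
      std::vector<int> idx(B);
      IntegerVector yb(B);
      for (int i = 0; i < B; ++i) {
        idx[i] = order(s + i, ep) - 1;
        yb[i] = y[idx[i]];
      }
      arma::fmat Xb = gather(x.begin(), d, idx);
      forward_batch(Xb, B, p, d, true, &rng, dropP, cc);
      double loss, acc;
      backward_batch(Xb, B, yb, p, d, cc, g, loss, acc);
      epLoss += loss * B; epAcc += acc * B;

      ++step;
      const float corr1 = (float)(1.0 - std::pow(0.9, (double)step));
      const float corr2 = (float)(1.0 - std::pow(0.999, (double)step));
      auto pm = p.mats(); auto gm = g.mats();
      auto mm = m.mats(); auto vm = v.mats();
      for (size_t k = 0; k < pm.size(); ++k) {
        arma::fmat& P = *pm[k]; arma::fmat& G = *gm[k];
        arma::fmat& M = *mm[k]; arma::fmat& V = *vm[k];
        for (arma::uword i = 0; i < P.n_elem; ++i) {
          M(i) = beta1 * M(i) + (1.0f - beta1) * G(i);
          V(i) = beta2 * V(i) + (1.0f - beta2) * G(i) * G(i);
          P(i) -= (float)lr * (M(i) / corr1) /
            (std::sqrt(V(i) / corr2) + epsA);
        }
      }
      auto pv = p.vecs(); auto gv = g.vecs();
      auto mv = m.vecs(); auto vv = v.vecs();
      for (size_t k = 0; k < pv.size(); ++k) {
        arma::fvec& P = *pv[k]; arma::fvec& G = *gv[k];
        arma::fvec& M = *mv[k]; arma::fvec& V = *vv[k];
        for (arma::uword i = 0; i < P.n_elem; ++i) {
          M(i) = beta1 * M(i) + (1.0f - beta1) * G(i);
          V(i) = beta2 * V(i) + (1.0f - beta2) * G(i) * G(i);
          P(i) -= (float)lr * (M(i) / corr1) /
            (std::sqrt(V(i) / corr2) + epsA);
        }
      }
    }
    history(ep, 0) = epLoss / n;
    history(ep, 1) = epAcc / n;
    if (hasVal) {
      arma::mat prob = predict_all(valx.begin(), nVal, p, d, 8);
      double vl = 0.0; int vc = 0;
      for (int i = 0; i < nVal; ++i) {
        vl += -std::log(std::max(prob(i, valy[i]), 1e-12));
        if ((int)prob.row(i).index_max() == valy[i]) ++vc;
      }
      history(ep, 2) = vl / nVal;
      history(ep, 3) = (double)vc / nVal;
    } else {
      history(ep, 2) = NA_REAL;
      history(ep, 3) = NA_REAL;
    }
    epochsRun = ep + 1;
    if (patience > 0) {
      if (history(ep, 2) < bestVal - 1e-6) { bestVal = history(ep, 2); wait = 0; }
      else if (++wait >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  List outPar = List::create(
    _["W1"] = as_R(p.W1), _["b1"] = as_Rv(p.b1),
    _["W2"] = as_R(p.W2), _["b2"] = as_Rv(p.b2),
    _["W3"] = as_R(p.W3), _["b3"] = as_Rv(p.b3),
    _["W4"] = as_R(p.W4), _["b4"] = as_Rv(p.b4));
  return List::create(_["params"] = outPar, _["history"] = history,
                      _["epochsRun"] = epochsRun);
}
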