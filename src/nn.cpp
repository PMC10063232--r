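// Dilated residual convolutional network over amino-acid sequences.
//
// Layout: an initial kernel-size, dilation-1 convolution lifts the 20-dim
// one-hot input to `filters` channels, followed by `num_res_layers`
// pre-activation bottleneck residual blocks
//   block(x) = x + Wp( relu(LN2( Wd( relu(LN1(x)) ) )) )
// where Wd is a dilated convolution to filters*bottleneck channels and Wp a
// kernel-1 width-restoring convolution.  Per-residue features are collapsed
// by a masked mean into one embedding, and an affine head yields per-label
// logits -> element-wise sigmoid probabilities.
//
// Sequences are processed one at a time (optionally with trailing padding,
// which is masked out after every layer so that a padded run reproduces the
// unpadded one exactly).  Convolutions are im2col + GEMM, so the heavy
// lifting is BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NAA = 20;
static const double LN_EPS = 1e-5;

struct Dims {
  int F;     // filters
  int Fb;    // bottleneck width
  int K;     // kernel size
  int V;     // vocabulary size
  int NB;    // number of residual blocks
  int RATE;  // dilation rate
  int FD;    // first dilated layer (1-indexed)
  int NORM;  // 1 = per-position layer norm, 0 = none
};

static Dims get_dims(const Rcpp::IntegerVector& d) {
  Dims dm;
  dm.F = d["filters"]; dm.Fb = d["bottleneck"]; dm.K = d["kernel"];
  dm.V = d["vocab"]; dm.NB = d["blocks"]; dm.RATE = d["rate"];
  dm.FD = d["first_dilated"]; dm.NORM = d["norm"];
  return dm;
}

static int block_dilation(const Dims& dm, int l1) {  // l1 is 1-indexed
  if (l1 < dm.FD) return 1;
  int d = 1;
  for (int i = 0; i < l1 - dm.FD + 1; ++i) d *= dm.RATE;
  return d;
}

// Parameter views over a flat vector (no copies).
struct BlockPar { mat g1, be1, Wd, bd, g2, be2, Wp, bp; };
struct Par {
  mat W_in, b_in, Wh, bh;
  std::vector<BlockPar> blk;
};

static Par make_views(double* p, const Dims& dm) {
  Par par;
  size_t off = 0;
  auto take = [&](int r, int c) {
    mat m(p + off, r, c, false, true);
    off += (size_t)r * c;
    return m;
  };
  par.W_in = take(dm.F, dm.K * NAA);
  par.b_in = take(dm.F, 1);
  par.blk.reserve(dm.NB);  // no reallocation: views must keep aliasing theta
  for (int l = 0; l < dm.NB; ++l) {
    par.blk.emplace_back();
    BlockPar& b = par.blk.back();
    b.g1 = take(dm.F, 1);  b.be1 = take(dm.F, 1);
    b.Wd = take(dm.Fb, dm.K * dm.F); b.bd = take(dm.Fb, 1);
    b.g2 = take(dm.Fb, 1); b.be2 = take(dm.Fb, 1);
    b.Wp = take(dm.F, dm.Fb); b.bp = take(dm.F, 1);
  }
  par.Wh = take(dm.V, dm.F);
  par.bh = take(dm.V, 1);
  return par;
}

static size_t param_count(const Dims& dm) {
  size_t n = (size_t)dm.F * dm.K * NAA + dm.F;
  n += (size_t)dm.NB * (2 * dm.F + (size_t)dm.Fb * dm.K * dm.F + dm.Fb
                        + 2 * dm.Fb + (size_t)dm.F * dm.Fb + dm.F);
  n += (size_t)dm.V * dm.F + dm.V;
  return n;
}

// [[Rcpp::export]]
Rcpp::List cpp_param_shapes(Rcpp::IntegerVector dims) {
  Dims dm = get_dims(dims);
  Rcpp::List out;
  auto add = [&](std::string nm, int r, int c, std::string kind) {
    out.push_back(Rcpp::List::create(
        Rcpp::Named("name") = nm, Rcpp::Named("nrow") = r,
        Rcpp::Named("ncol") = c, Rcpp::Named("kind") = kind));
  };
  add("W_in", dm.F, dm.K * NAA, "conv");
  add("b_in", dm.F, 1, "bias");
  for (int l = 1; l <= dm.NB; ++l) {
    std::string s = std::to_string(l);
    add("g1." + s, dm.F, 1, "gain");
    add("be1." + s, dm.F, 1, "bias");
    add("Wd." + s, dm.Fb, dm.K * dm.F, "conv");
    add("bd." + s, dm.Fb, 1, "bias");
    add("g2." + s, dm.Fb, 1, "gain");
    add("be2." + s, dm.Fb, 1, "bias");
    add("Wp." + s, dm.F, dm.Fb, "conv");
    add("bp." + s, dm.F, 1, "bias");
  }
  add("Wh", dm.V, dm.F, "head");
  add("bh", dm.V, 1, "bias");
  return out;
}

// im2col for a (C x Lp) signal: output (K*C x Lp); out-of-range taps are 0.
static mat im2col(const mat& X, int K, int dil) {
  const int C = X.n_rows, Lp = X.n_cols, half = K / 2;
  mat col(K * C, Lp, fill::zeros);
  for (int j = 0; j < K; ++j) {
    int off = (j - half) * dil;
    int lo = std::max(0, -off), hi = std::min(Lp, Lp - off);
    if (lo < hi)
      col.submat(j * C, lo, (j + 1) * C - 1, hi - 1) =
          X.cols(lo + off, hi - 1 + off);
  }
  return col;
}

static void col2im_add(mat& dX, const mat& dCol, int K, int dil) {
  const int C = dX.n_rows, Lp = dX.n_cols, half = K / 2;
  for (int j = 0; j < K; ++j) {
    int off = (j - half) * dil;
    int lo = std::max(0, -off), hi = std::min(Lp, Lp - off);
    if (lo < hi)
      dX.cols(lo + off, hi - 1 + off) +=
          dCol.submat(j * C, lo, (j + 1) * C - 1, hi - 1);
  }
}

static void mask_cols(mat& X, int L) {
  if ((int)X.n_cols > L) X.cols(L, X.n_cols - 1).zeros();
}

// Layer norm over channels, per position; returns y, caches xhat and inv std.
static mat ln_forward(const mat& X, const mat& g, const mat& be,
                      mat& xhat, rowvec& inv) {
  rowvec mu = mean(X, 0);
  rowvec v = mean(square(X.each_row() - mu), 0);
  inv = 1.0 / sqrt(v + LN_EPS);
  xhat = (X.each_row() - mu).each_row() % inv;
  mat y = xhat.each_col() % g.col(0);
  y.each_col() += be.col(0);
  return y;
}

static mat ln_backward(const mat& dy, const mat& xhat, const rowvec& inv,
                       const mat& g, mat& dg, mat& dbe) {
  dg += sum(dy % xhat, 1);
  dbe += sum(dy, 1);
  mat dxh = dy.each_col() % g.col(0);
  rowvec m1 = mean(dxh, 0);
  rowvec m2 = mean(dxh % xhat, 0);
  mat dx = dxh.each_row() - m1;
  dx -= xhat.each_row() % m2;
  dx.each_row() %= inv;
  return dx;
}

struct BlockCache {
  mat xhat1, R1, xhat2, R2;
  rowvec inv1, inv2;
};

struct FwdCache {
  mat X0;                      // one-hot, NAA x Lp
  mat h_in;                    // after input conv
  std::vector<mat> h;          // residual stream after each block
  std::vector<BlockCache> bc;
  vec e, z, p;
  int L, Lp;
};

// seq: 0-based integer codes; pad: extra masked trailing positions.
static void forward_one(const Par& par, const Dims& dm,
                        const Rcpp::IntegerVector& seq, int pad,
                        FwdCache& C) {
  const int L = seq.size(), Lp = L + pad;
  C.L = L; C.Lp = Lp;
  C.X0.zeros(NAA, Lp);
  for (int i = 0; i < L; ++i) {
    int a = seq[i];
    if (a < 0 || a >= NAA) Rcpp::stop("residue code out of range at position %d", i + 1);
    C.X0(a, i) = 1.0;
  }
  mat col0 = im2col(C.X0, dm.K, 1);
  mat h = par.W_in * col0;
  h.each_col() += par.b_in.col(0);
  mask_cols(h, L);
  C.h_in = h;
  C.h.clear(); C.bc.assign(dm.NB, BlockCache());
  for (int l = 0; l < dm.NB; ++l) {
    BlockCache& bc = C.bc[l];
    const BlockPar& bp = par.blk[l];
    int dil = block_dilation(dm, l + 1);
    mat U = dm.NORM ? ln_forward(h, bp.g1, bp.be1, bc.xhat1, bc.inv1) : h;
    bc.R1 = U;
    bc.R1.elem(find(bc.R1 < 0)).zeros();
    mask_cols(bc.R1, L);
    mat Dv = bp.Wd * im2col(bc.R1, dm.K, dil);
    Dv.each_col() += bp.bd.col(0);
    mat U2 = dm.NORM ? ln_forward(Dv, bp.g2, bp.be2, bc.xhat2, bc.inv2) : Dv;
    bc.R2 = U2;
    bc.R2.elem(find(bc.R2 < 0)).zeros();
    mask_cols(bc.R2, L);
    mat G = bp.Wp * bc.R2;
    G.each_col() += bp.bp.col(0);
    h += G;
    mask_cols(h, L);
    C.h.push_back(h);
  }
  C.e = sum(h.cols(0, L - 1), 1) / (double)L;
  C.z = par.Wh * C.e + par.bh.col(0);
  C.p = 1.0 / (1.0 + exp(-C.z));
}

// Backprop from dz; accumulates into gpar.
static void backward_one(const Par& par, Par& gpar, const Dims& dm,
                         FwdCache& C, const vec& dz) {
  const int L = C.L;
  gpar.Wh += dz * C.e.t();
  gpar.bh += dz;
  vec de = par.Wh.t() * dz;
  mat dh(dm.F, C.Lp, fill::zeros);
  dh.cols(0, L - 1) = repmat(de / (double)L, 1, L);
  for (int l = dm.NB - 1; l >= 0; --l) {
    BlockCache& bc = C.bc[l];
    const BlockPar& bp = par.blk[l];
    BlockPar& gb = gpar.blk[l];
    int dil = block_dilation(dm, l + 1);
    // through G = Wp * R2 + bp
    gb.Wp += dh * bc.R2.t();
    gb.bp += sum(dh, 1);
    mat dR2 = bp.Wp.t() * dh;
    mat dU2 = dR2;
    dU2.elem(find(bc.R2 <= 0)).zeros();
    mat dDv = dm.NORM
        ? ln_backward(dU2, bc.xhat2, bc.inv2, bp.g2, gb.g2, gb.be2)
        : dU2;
    mat R1col = im2col(bc.R1, dm.K, dil);
    gb.Wd += dDv * R1col.t();
    gb.bd += sum(dDv, 1);
    mat dR1(dm.F, C.Lp, fill::zeros);
    col2im_add(dR1, bp.Wd.t() * dDv, dm.K, dil);
    mask_cols(dR1, L);
    mat dU = dR1;
    dU.elem(find(bc.R1 <= 0)).zeros();
    mat dhb = dm.NORM
        ? ln_backward(dU, bc.xhat1, bc.inv1, bp.g1, gb.g1, gb.be1)
        : dU;
    dh += dhb;  // residual: gradient flows both through the block and around it
    mask_cols(dh, L);
  }
  gpar.b_in += sum(dh, 1);
  mat col0 = im2col(C.X0, dm.K, 1);
  gpar.W_in += dh * col0.t();
}

// [[Rcpp::export]]
double cpp_param_length(Rcpp::IntegerVector dims) {
  return (double)param_count(get_dims(dims));
}

// [[Rcpp::export]]
Rcpp::List cpp_forward_one(Rcpp::NumericVector theta, Rcpp::IntegerVector dims,
                           Rcpp::IntegerVector seq, int pad = 0,
                           bool want_features = false) {
  Dims dm = get_dims(dims);
  if ((size_t)theta.size() != param_count(dm)) Rcpp::stop("parameter vector has wrong length");
  Par par = make_views(theta.begin(), dm);
  FwdCache C;
  forward_one(par, dm, seq, pad, C);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("logits") = Rcpp::NumericVector(C.z.begin(), C.z.end()),
      Rcpp::Named("probabilities") =
          Rcpp::NumericVector(C.p.begin(), C.p.end()),
      Rcpp::Named("embedding") = Rcpp::NumericVector(C.e.begin(), C.e.end()));
  if (want_features) {
    mat feat = C.h.back().cols(0, C.L - 1).t();  // L x F
    out["features"] = feat;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_predict_many(Rcpp::NumericVector theta, Rcpp::IntegerVector dims,
                            Rcpp::List seqs) {
  Dims dm = get_dims(dims);
  if ((size_t)theta.size() != param_count(dm)) Rcpp::stop("parameter vector has wrong length");
  Par par = make_views(theta.begin(), dm);
  const int B = seqs.size();
  mat P(B, dm.V), E(B, dm.F);
  FwdCache C;
  for (int b = 0; b < B; ++b) {
    forward_one(par, dm, seqs[b], 0, C);
    P.row(b) = C.p.t();
    E.row(b) = C.e.t();
  }
  return Rcpp::List::create(Rcpp::Named("probabilities") = P,
                            Rcpp::Named("embeddings") = E);
}

// Mean-over-vocabulary binary cross-entropy, averaged over the batch.
// Y: B x V 0/1 matrix.
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(Rcpp::NumericVector theta, Rcpp::IntegerVector dims,
                          Rcpp::List seqs, arma::mat Y) {
  Dims dm = get_dims(dims);
  if ((size_t)theta.size() != param_count(dm)) Rcpp::stop("parameter vector has wrong length");
  const int B = seqs.size();
  if ((int)Y.n_rows != B || (int)Y.n_cols != dm.V)
    Rcpp::stop("label matrix shape mismatch");
  Par par = make_views(theta.begin(), dm);
  Rcpp::NumericVector grad((R_xlen_t)param_count(dm));
  Par gpar = make_views(grad.begin(), dm);
  const double eps = 1e-7;
  double loss = 0.0;
  FwdCache C;
  for (int b = 0; b < B; ++b) {
    forward_one(par, dm, seqs[b], 0, C);
    vec y = Y.row(b).t();
    vec pc = clamp(C.p, eps, 1.0 - eps);
    loss += as_scalar(mean(-(y % log(pc) + (1.0 - y) % log(1.0 - pc))));
    vec dz = (C.p - y) / ((double)dm.V * B);
    backward_one(par, gpar, dm, C, dz);
  }
  loss /= B;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
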