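// Hot-path kernels for the transformer encoders: batched multi-head
// attention over equal-length segments, LayerNorm and GELU with their
// backward passes. Matrix products go through Armadillo/BLAS; the R side
// keeps orchestration, caches and parameter trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;
using arma::rowvec;

// Row-wise softmax stabilised by the global maximum.
static inline void softmax_rows_inplace(mat& S) {
  S -= S.max();
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
}

// [[Rcpp::export(rng = false)]]
List cpp_msa_fwd(const arma::mat& X, const arma::mat& Uqkv, const arma::mat& Umsa,
                 int k, int dh, int nseg, int ntok) {
  mat QKV = X * Uqkv;
  mat heads(X.n_rows, (arma::uword)(k * dh), arma::fill::zeros);
  cube attn(ntok, ntok, (arma::uword)(k * nseg));
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < k; ++h) {
    const int off = h * 3 * dh;
    for (int s = 0; s < nseg; ++s) {
      const int r0 = s * ntok, r1 = (s + 1) * ntok - 1;
      mat P = QKV.submat(r0, off, r1, off + dh - 1) *
              QKV.submat(r0, off + dh, r1, off + 2 * dh - 1).t() * scale;
      softmax_rows_inplace(P);
      attn.slice((arma::uword)(s * k + h)) = P;
      heads.submat(r0, h * dh, r1, (h + 1) * dh - 1) =
          P * QKV.submat(r0, off + 2 * dh, r1, off + 3 * dh - 1);
    }
  }
  return List::create(_["Y"] = heads * Umsa, _["QKV"] = QKV,
                      _["heads"] = heads, _["attn"] = attn);
}

// [[Rcpp::export(rng = false)]]
List cpp_msa_bwd(const arma::mat& dY, const arma::mat& X, const arma::mat& QKV,
                 const arma::mat& heads, const arma::cube& attn, const arma::mat& Uqkv,
                 const arma::mat& Umsa, int k, int dh, int nseg, int ntok) {
  mat dUmsa = heads.t() * dY;
  mat dheads = dY * Umsa.t();
  mat dQKV(QKV.n_rows, QKV.n_cols, arma::fill::zeros);
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < k; ++h) {
    const int off = h * 3 * dh;
    for (int s = 0; s < nseg; ++s) {
      const int r0 = s * ntok, r1 = (s + 1) * ntok - 1;
      const mat& P = attn.slice((arma::uword)(s * k + h));
      mat dO = dheads.submat(r0, h * dh, r1, (h + 1) * dh - 1);
      mat dP = dO * QKV.submat(r0, off + 2 * dh, r1, off + 3 * dh - 1).t();
      vec rs = arma::sum(dP % P, 1);
      mat dS = P % (dP.each_col() - rs);
      dS *= scale;
      dQKV.submat(r0, off, r1, off + dh - 1) =
          dS * QKV.submat(r0, off + dh, r1, off + 2 * dh - 1);
      dQKV.submat(r0, off + dh, r1, off + 2 * dh - 1) =
          dS.t() * QKV.submat(r0, off, r1, off + dh - 1);
      dQKV.submat(r0, off + 2 * dh, r1, off + 3 * dh - 1) = P.t() * dO;
    }
  }
  return List::create(_["dX"] = dQKV * Uqkv.t(),
                      _["dUqkv"] = X.t() * dQKV, _["dUmsa"] = dUmsa);
}

// [[Rcpp::export(rng = false)]]
List cpp_ln_fwd(const arma::mat& X, const arma::rowvec& g, const arma::rowvec& b, double eps) {
  vec mu = arma::mean(X, 1);
  mat xhat = X.each_col() - mu;
  vec inv = 1.0 / arma::sqrt(arma::mean(xhat % xhat, 1) + eps);
  xhat.each_col() %= inv;
  mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(rng = false)]]
List cpp_ln_bwd(const arma::mat& dY, const arma::mat& xhat, const arma::vec& inv,
                const arma::rowvec& g) {
  mat dxhat = dY.each_row() % g;
  rowvec dg = arma::sum(dY % xhat, 0);
  rowvec db = arma::sum(dY, 0);
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// Sigmoid-gated GELU approximation x * sigma(1.702 x).
// [[Rcpp::export(rng = false)]]
List cpp_gelu_fwd(const arma::mat& X) {
  mat S = 1.0 / (1.0 + arma::exp(-1.702 * X));
  return List::create(_["Y"] = X % S, _["S"] = S);
}

// [[Rcpp::export(rng = false)]]
arma::mat cpp_gelu_bwd(const arma::mat& dY, const arma::mat& X, const arma::mat& S) {
  return dY % (S + 1.702 * (X % S % (1.0 - S)));
}

// Y = X W + 1 b'
// [[Rcpp::export(rng = false)]]
arma::mat cpp_linear(const arma::mat& X, const arma::mat& W, const arma::rowvec& b) {
  mat Y = X * W;
  Y.each_row() += b;
  return Y;
}

// ---- whole-encoder kernels (training fast path) ---------------------------
// One call per encoder pass; caches cross the boundary once as a List.

static void ln_fwd_inplace(const mat& X, const rowvec& g, const rowvec& b,
                           double eps, mat& Y, mat& xhat, vec& inv) {
  vec mu = arma::mean(X, 1);
  xhat = X.each_col() - mu;
  inv = 1.0 / arma::sqrt(arma::mean(xhat % xhat, 1) + eps);
  xhat.each_col() %= inv;
  Y = xhat.each_row() % g;
  Y.each_row() += b;
}

static mat ln_bwd_core(const mat& dY, const mat& xhat, const vec& inv,
                       const rowvec& g, rowvec& dg, rowvec& db) {
  mat dxhat = dY.each_row() % g;
  dg = arma::sum(dY % xhat, 0);
  db = arma::sum(dY, 0);
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  return dX;
}

static void msa_core_fwd(const mat& Xin, const mat& Uqkv, const mat& Umsa,
                         int k, int dh, int nseg, int ntok,
                         mat& Y, mat& QKV, mat& heads, cube& attn) {
  QKV = Xin * Uqkv;
  heads.zeros(Xin.n_rows, (arma::uword)(k * dh));
  attn.set_size(ntok, ntok, (arma::uword)(k * nseg));
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < k; ++h) {
    const int off = h * 3 * dh;
    for (int s = 0; s < nseg; ++s) {
      const int r0 = s * ntok, r1 = (s + 1) * ntok - 1;
      mat P = QKV.submat(r0, off, r1, off + dh - 1) *
              QKV.submat(r0, off + dh, r1, off + 2 * dh - 1).t() * scale;
      softmax_rows_inplace(P);
      attn.slice((arma::uword)(s * k + h)) = P;
      heads.submat(r0, h * dh, r1, (h + 1) * dh - 1) =
          P * QKV.submat(r0, off + 2 * dh, r1, off + 3 * dh - 1);
    }
  }
  Y = heads * Umsa;
}

// [[Rcpp::export(rng = false)]]
List cpp_encoder_fwd(const arma::mat& X0, const List& blocks,
                     const arma::rowvec& lnf_g, const arma::rowvec& lnf_b,
                     int k, int dh, int nseg, int ntok, double eps,
                     bool keep_attn) {
  mat X = X0;
  const int L = blocks.size();
  List caches(L);
  List attns(L);
  for (int l = 0; l < L; ++l) {
    List bp = blocks[l];
    rowvec ln1_g = bp["ln1_g"], ln1_b = bp["ln1_b"];
    rowvec ln2_g = bp["ln2_g"], ln2_b = bp["ln2_b"];
    mat Uqkv = bp["Uqkv"], Umsa = bp["Umsa"];
    mat W1 = bp["W1"], W2 = bp["W2"];
    rowvec b1 = bp["b1"], b2 = bp["b2"];
    mat l1Y, xhat1; vec inv1;
    ln_fwd_inplace(X, ln1_g, ln1_b, eps, l1Y, xhat1, inv1);
    mat attY, QKV, heads; cube attn;
    msa_core_fwd(l1Y, Uqkv, Umsa, k, dh, nseg, ntok, attY, QKV, heads, attn);
    mat X1 = X + attY;
    mat l2Y, xhat2; vec inv2;
    ln_fwd_inplace(X1, ln2_g, ln2_b, eps, l2Y, xhat2, inv2);
    mat f1Y = l2Y * W1;
    f1Y.each_row() += b1;
    mat S = 1.0 / (1.0 + arma::exp(-1.702 * f1Y));
    mat g1Y = f1Y % S;
    mat f2Y = g1Y * W2;
    f2Y.each_row() += b2;
    mat Y = X1 + f2Y;
    caches[l] = List::create(
        _["xhat1"] = xhat1, _["inv1"] = inv1, _["l1Y"] = l1Y,
        _["QKV"] = QKV, _["heads"] = heads, _["attn"] = attn,
        _["xhat2"] = xhat2, _["inv2"] = inv2, _["l2Y"] = l2Y,
        _["f1Y"] = f1Y, _["S"] = S, _["g1Y"] = g1Y);
    if (keep_attn) attns[l] = attn;
    X = Y;
  }
  mat Yf, xhatf; vec invf;
  ln_fwd_inplace(X, lnf_g, lnf_b, eps, Yf, xhatf, invf);
  return List::create(_["Y"] = Yf, _["caches"] = caches,
                      _["xhatf"] = xhatf, _["invf"] = invf,
                      _["attn"] = attns);
}

// [[Rcpp::export(rng = false)]]
List cpp_encoder_bwd(const arma::mat& dYin, const List& blocks,
                     const List& caches, const arma::mat& xhatf,
                     const arma::vec& invf, const arma::rowvec& lnf_g,
                     int k, int dh, int nseg, int ntok) {
  rowvec lnf_dg, lnf_db;
  mat dX = ln_bwd_core(dYin, xhatf, invf, lnf_g, lnf_dg, lnf_db);
  const int L = blocks.size();
  List grads(L);
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int l = L - 1; l >= 0; --l) {
    List bp = blocks[l];
    List ch = caches[l];
    rowvec ln1_g = bp["ln1_g"], ln2_g = bp["ln2_g"];
    mat Uqkv = bp["Uqkv"], Umsa = bp["Umsa"];
    mat W1 = bp["W1"], W2 = bp["W2"];
    mat xhat1 = ch["xhat1"], l1Y = ch["l1Y"], QKV = ch["QKV"],
        heads = ch["heads"], xhat2 = ch["xhat2"], l2Y = ch["l2Y"],
        f1Y = ch["f1Y"], S = ch["S"], g1Y = ch["g1Y"];
    vec inv1 = ch["inv1"], inv2 = ch["inv2"];
    cube attn = ch["attn"];
    // mlp branch
    mat dW2 = g1Y.t() * dX;
    rowvec db2 = arma::sum(dX, 0);
    mat dg1 = dX * W2.t();
    mat df1 = dg1 % (S + 1.702 * (f1Y % S % (1.0 - S)));
    mat dW1 = l2Y.t() * df1;
    rowvec db1 = arma::sum(df1, 0);
    mat dl2 = df1 * W1.t();
    rowvec ln2_dg, ln2_db;
    mat dX1 = ln_bwd_core(dl2, xhat2, inv2, ln2_g, ln2_dg, ln2_db);
    dX1 += dX;                       // residual around the MLP
    // attention branch
    mat dUmsa = heads.t() * dX1;
    mat dheads = dX1 * Umsa.t();
    mat dQKV(QKV.n_rows, QKV.n_cols, arma::fill::zeros);
    for (int h = 0; h < k; ++h) {
      const int off = h * 3 * dh;
      for (int s = 0; s < nseg; ++s) {
        const int r0 = s * ntok, r1 = (s + 1) * ntok - 1;
        const mat& P = attn.slice((arma::uword)(s * k + h));
        mat dO = dheads.submat(r0, h * dh, r1, (h + 1) * dh - 1);
        mat dP = dO * QKV.submat(r0, off + 2 * dh, r1, off + 3 * dh - 1).t();
        vec rs = arma::sum(dP % P, 1);
        mat dS = P % (dP.each_col() - rs);
        dS *= scale;
        dQKV.submat(r0, off, r1, off + dh - 1) =
            dS * QKV.submat(r0, off + dh, r1, off + 2 * dh - 1);
        dQKV.submat(r0, off + dh, r1, off + 2 * dh - 1) =
            dS.t() * QKV.submat(r0, off, r1, off + dh - 1);
        dQKV.submat(r0, off + 2 * dh, r1, off + 3 * dh - 1) = P.t() * dO;
      }
    }
    mat dl1 = dQKV * Uqkv.t();
    mat dUqkv = l1Y.t() * dQKV;
    rowvec ln1_dg, ln1_db;
    mat dXl = ln_bwd_core(dl1, xhat1, inv1, ln1_g, ln1_dg, ln1_db);
    dX = dX1 + dXl;                  // residual around the attention
    grads[l] = List::create(
        _["ln1_g"] = ln1_dg, _["ln1_b"] = ln1_db,
        _["Uqkv"] = dUqkv, _["Umsa"] = dUmsa,
        _["ln2_g"] = ln2_dg, _["ln2_b"] = ln2_db,
        _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2, _["b2"] = db2);
  }
  return List::create(_["dX"] = dX, _["grads"] = grads,
                      _["lnf_g"] = lnf_dg, _["lnf_b"] = lnf_db);
}

// ---- AdamW over the nested parameter tree ---------------------------------
// One call per optimizer step: recursively updates every numeric leaf of
// the (params, grads, m, v) trees with decoupled weight decay, optional
// global-norm clipping, and the same arithmetic as the reference R loop.

// Per-leaf partial sums accumulated across the flattened leaf sequence
// with extended-precision accumulators — the same grouping and accumulator
// width as computing each leaf's sum(x*x) in R and summing the totals.
static void tree_sumsq_acc(const List& g, long double& s) {
  for (int i = 0; i < g.size(); ++i) {
    SEXP el = g[i];
    if (Rf_isNewList(el)) {
      tree_sumsq_acc(List(el), s);
    } else {
      NumericVector x(el);
      long double leaf = 0.0L;
      for (double xi : x) leaf += xi * xi;
      s += (double)leaf;
    }
  }
}

static void adamw_walk(List p, const List& g, List m, List v,
                       double gscale, double lr, double b1, double b2,
                       double bc1, double bc2, double eps, double wd,
                       const std::vector<std::string>& no_decay,
                       const std::string& name) {
  CharacterVector nms = p.names();
  for (int i = 0; i < p.size(); ++i) {
    std::string nm = nms.size() > i ? std::string(nms[i]) : "";
    SEXP el = p[i];
    if (Rf_isNewList(el)) {
      adamw_walk(List(el), List(g[i]), List(m[i]), List(v[i]), gscale, lr,
                 b1, b2, bc1, bc2, eps, wd, no_decay, nm);
    } else {
      NumericVector pp(el), gg(g[i]), mm(m[i]), vv(v[i]);
      const bool decay =
          wd > 0 &&
          std::find(no_decay.begin(), no_decay.end(), nm) == no_decay.end();
      for (R_xlen_t j = 0; j < pp.size(); ++j) {
        const double gj = gg[j] * gscale;
        mm[j] = b1 * mm[j] + (1 - b1) * gj;
        vv[j] = b2 * vv[j] + (1 - b2) * gj * gj;
        const double upd = (mm[j] / bc1) / (std::sqrt(vv[j] / bc2) + eps);
        double pj = pp[j];
        if (decay) pj -= lr * wd * pj;
        pp[j] = pj - lr * upd;
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
List cpp_adamw_step(List p, List g, List m, List v, int t, double lr,
                    double b1, double b2, double eps, double wd,
                    std::vector<std::string> no_decay, double clip_norm) {
  // deep-duplicate so caller-held references stay untouched
  p = clone(p); m = clone(m); v = clone(v);
  double gscale = 1.0;
  if (R_finite(clip_norm)) {
    long double ss = 0.0L;
    tree_sumsq_acc(g, ss);
    const double gn = std::sqrt((double)ss);
    if (gn > clip_norm) gscale = clip_norm / gn;
  }
  const double bc1 = 1 - std::pow(b1, (double)t);
  const double bc2 = 1 - std::pow(b2, (double)t);
  adamw_walk(p, g, m, v, gscale, lr, b1, b2, bc1, bc2, eps, wd, no_decay,
             "");
  return List::create(_["p"] = p, _["m"] = m, _["v"] = v);
}
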