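// Fused forward/backward pass of one post-norm transformer layer over a
// batch of block-packed sequences: QKV projection, block-local multi-head
// attention, output projection, residual dropout, layer norm, position-wise
// feed-forward (ReLU), residual dropout, layer norm. Heavy matrix products
// go through BLAS (armadillo); attention and layer-norm use the dedicated
// kernels in this directory's style. Dropout masks are drawn from R's RNG
// so seeding semantics match the R level.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// forward declarations of kernels defined in attention.cpp
List mha_forward_cpp(const NumericMatrix& Q, const NumericMatrix& K,
                     const NumericMatrix& V,
                     const IntegerVector& starts, const IntegerVector& lens,
                     const int H, const bool causal);
List mha_backward_cpp(const NumericMatrix& dCtx, const NumericVector& Pstore,
                      const NumericMatrix& Q, const NumericMatrix& K,
                      const NumericMatrix& V,
                      const IntegerVector& starts, const IntegerVector& lens,
                      const int H);
List ln_forward_cpp(const NumericMatrix& R, const NumericVector& g,
                    const NumericVector& b, const double eps);
List ln_backward_cpp(const NumericMatrix& dY, const NumericMatrix& xhat,
                     const NumericVector& inv, const NumericVector& g);

static arma::mat as_arma(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(&m[0]), m.nrow(), m.ncol(), false, true);
}

static NumericMatrix proj(const NumericMatrix& X, const NumericMatrix& W,
                          const NumericVector& b) {
  const int N = X.nrow(), dout = W.ncol();
  NumericMatrix out(N, dout);
  arma::mat O(&out[0], N, dout, false, true);
  O = as_arma(X) * as_arma(W);
  double* op = &out[0];
  for (int j = 0; j < dout; ++j) {
    const double bj = b[j];
    double* col = op + (R_xlen_t)j * N;
    for (int i = 0; i < N; ++i) col[i] += bj;
  }
  return out;
}

// inverted dropout mask from R's RNG, or NULL when inactive
static SEXP make_dropout(const int N, const int d, const double p,
                         const bool train) {
  if (!train || p <= 0) return R_NilValue;
  NumericMatrix m(N, d);
  const double scale = 1.0 / (1.0 - p);
  double* mp = &m[0];
  GetRNGstate();
  for (R_xlen_t i = 0; i < (R_xlen_t)N * d; ++i)
    mp[i] = (unif_rand() >= p) ? scale : 0.0;
  PutRNGstate();
  return m;
}

static NumericMatrix apply_mask_add(const NumericMatrix& X,
                                    const NumericMatrix& A, SEXP mask) {
  const int N = X.nrow(), d = X.ncol();
  NumericMatrix out(N, d);
  const double *xp = &X[0], *ap = &A[0];
  double* op = &out[0];
  const R_xlen_t n = (R_xlen_t)N * d;
  if (mask == R_NilValue) {
    for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] + ap[i];
  } else {
    NumericMatrix m(mask);
    const double* mp = &m[0];
    for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] + ap[i] * mp[i];
  }
  return out;
}

// [[Rcpp::export]]
List layer_forward_cpp(const NumericMatrix& X, const IntegerVector& starts,
                       const IntegerVector& lens, const int H,
                       const bool causal, const List& Wl,
                       const double dropout_p, const bool train,
                       const double ln_eps) {
  NumericMatrix Q = proj(X, Wl["wq"], Wl["bq"]);
  NumericMatrix K = proj(X, Wl["wk"], Wl["bk"]);
  NumericMatrix V = proj(X, Wl["wv"], Wl["bv"]);
  List at = mha_forward_cpp(Q, K, V, starts, lens, H, causal);
  NumericMatrix Ctx = at["Ctx"];
  NumericMatrix A = proj(Ctx, Wl["wo"], Wl["bo"]);
  RObject m1 = make_dropout(X.nrow(), X.ncol(), dropout_p, train);
  NumericMatrix R1 = apply_mask_add(X, A, m1);
  List ln1 = ln_forward_cpp(R1, Wl["ln1_g"], Wl["ln1_b"], ln_eps);
  NumericMatrix H1 = ln1["out"];
  NumericMatrix Z1 = proj(H1, Wl["ffn_w1"], Wl["ffn_b1"]);
  NumericMatrix Arelu(Z1.nrow(), Z1.ncol());
  {
    const double* zp = &Z1[0];
    double* ap = &Arelu[0];
    const R_xlen_t n = (R_xlen_t)Z1.nrow() * Z1.ncol();
    for (R_xlen_t i = 0; i < n; ++i) ap[i] = zp[i] > 0 ? zp[i] : 0.0;
  }
  NumericMatrix Fo = proj(Arelu, Wl["ffn_w2"], Wl["ffn_b2"]);
  RObject m2 = make_dropout(X.nrow(), X.ncol(), dropout_p, train);
  NumericMatrix R2 = apply_mask_add(H1, Fo, m2);
  List ln2 = ln_forward_cpp(R2, Wl["ln2_g"], Wl["ln2_b"], ln_eps);
  return List::create(
    _["out"] = ln2["out"],
    _["Q"] = Q, _["K"] = K, _["V"] = V, _["P"] = at["P"], _["Ctx"] = Ctx,
    _["m1"] = m1, _["m2"] = m2,
    _["xhat1"] = ln1["xhat"], _["inv1"] = ln1["inv"],
    _["H1"] = H1, _["Z1"] = Z1, _["Arelu"] = Arelu,
    _["xhat2"] = ln2["xhat"], _["inv2"] = ln2["inv"]);
}

// elementwise product (gradient through a dropout mask)
static NumericMatrix mask_mult(const NumericMatrix& dY, SEXP mask) {
  if (mask == R_NilValue) return dY;
  NumericMatrix m(mask);
  NumericMatrix out(dY.nrow(), dY.ncol());
  const double *dp = &dY[0], *mp = &m[0];
  double* op = &out[0];
  const R_xlen_t n = (R_xlen_t)dY.nrow() * dY.ncol();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = dp[i] * mp[i];
  return out;
}

// [[Rcpp::export]]
List layer_backward_cpp(const NumericMatrix& dOut, const List& cache,
                        const NumericMatrix& X, const IntegerVector& starts,
                        const IntegerVector& lens, const int H,
                        const List& Wl) {
  const int N = dOut.nrow(), d = dOut.ncol();
  // LN2
  List b2 = ln_backward_cpp(dOut, cache["xhat2"], cache["inv2"], Wl["ln2_g"]);
  NumericMatrix dR2 = b2["dX"];
  // FFN
  NumericMatrix dF = mask_mult(dR2, cache["m2"]);
  NumericMatrix Arelu = cache["Arelu"];
  NumericMatrix H1 = cache["H1"];
  NumericMatrix Z1 = cache["Z1"];
  arma::mat dFa = as_arma(dF);
  arma::mat dW2 = as_arma(Arelu).t() * dFa;
  arma::rowvec db2 = arma::sum(dFa, 0);
  arma::mat dArelu = dFa * as_arma((NumericMatrix)Wl["ffn_w2"]).t();
  {
    const double* zp = &Z1[0];
    double* ap = dArelu.memptr();
    const R_xlen_t n = (R_xlen_t)Z1.nrow() * Z1.ncol();
    for (R_xlen_t i = 0; i < n; ++i) if (zp[i] <= 0) ap[i] = 0.0;
  }
  arma::mat dW1 = as_arma(H1).t() * dArelu;
  arma::rowvec db1 = arma::sum(dArelu, 0);
  // dH1 = dR2 + dZ1 W1^T
  NumericMatrix dH1(N, d);
  {
    arma::mat dH1a(&dH1[0], N, d, false, true);
    dH1a = as_arma(dR2) + dArelu * as_arma((NumericMatrix)Wl["ffn_w1"]).t();
  }
  // LN1
  List b1 = ln_backward_cpp(dH1, cache["xhat1"], cache["inv1"], Wl["ln1_g"]);
  NumericMatrix dR1 = b1["dX"];
  NumericMatrix dA = mask_mult(dR1, cache["m1"]);
  // output projection
  NumericMatrix Ctx = cache["Ctx"];
  arma::mat dAa = as_arma(dA);
  arma::mat dWo = as_arma(Ctx).t() * dAa;
  arma::rowvec dbo = arma::sum(dAa, 0);
  NumericMatrix dCtx(N, d);
  {
    arma::mat dCa(&dCtx[0], N, d, false, true);
    dCa = dAa * as_arma((NumericMatrix)Wl["wo"]).t();
  }
  // attention
  List ab = mha_backward_cpp(dCtx, cache["P"], cache["Q"], cache["K"],
                             cache["V"], starts, lens, H);
  NumericMatrix dQ = ab["dQ"], dK = ab["dK"], dV = ab["dV"];
  arma::mat dQa = as_arma(dQ), dKa = as_arma(dK), dVa = as_arma(dV);
  arma::mat Xa = as_arma(X);
  arma::mat dWq = Xa.t() * dQa; arma::rowvec dbq = arma::sum(dQa, 0);
  arma::mat dWk = Xa.t() * dKa; arma::rowvec dbk = arma::sum(dKa, 0);
  arma::mat dWv = Xa.t() * dVa; arma::rowvec dbv = arma::sum(dVa, 0);
  // dX = dR1 + dQ Wq^T + dK Wk^T + dV Wv^T
  NumericMatrix dX(N, d);
  {
    arma::mat dXa(&dX[0], N, d, false, true);
    dXa = as_arma(dR1) +
      dQa * as_arma((NumericMatrix)Wl["wq"]).t() +
      dKa * as_arma((NumericMatrix)Wl["wk"]).t() +
      dVa * as_arma((NumericMatrix)Wl["wv"]).t();
  }
  return List::create(
    _["dX"] = dX,
    _["wq"] = dWq, _["bq"] = NumericVector(dbq.begin(), dbq.end()),
    _["wk"] = dWk, _["bk"] = NumericVector(dbk.begin(), dbk.end()),
    _["wv"] = dWv, _["bv"] = NumericVector(dbv.begin(), dbv.end()),
    _["wo"] = dWo, _["bo"] = NumericVector(dbo.begin(), dbo.end()),
    _["ln1_g"] = b1["dg"], _["ln1_b"] = b1["db"],
    _["ffn_w1"] = dW1, _["ffn_b1"] = NumericVector(db1.begin(), db1.end()),
    _["ffn_w2"] = dW2, _["ffn_b2"] = NumericVector(db2.begin(), db2.end()),
    _["ln2_g"] = b2["dg"], _["ln2_b"] = b2["db"]);
}
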