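// Grouped element-wise max over contribution rows: each visit's embedding is
// the max over its stacked contribution embeddings (codes, visit type, date
// bucket). Contributions arrive sorted by visit id. The forward pass records
// the argmax row per (visit, dimension); the backward pass scatters the
// upstream gradient onto exactly those rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List maxpool_forward_cpp(const arma::mat& M, const IntegerVector& vis,
                         const int n_vis) {
  const int d = M.n_cols;
  const R_xlen_t n = M.n_rows;
  arma::mat E(n_vis, d);
  E.fill(-arma::datum::inf);
  IntegerMatrix Amat(n_vis, d);
  for (R_xlen_t r = 0; r < n; ++r) {
    const int v = vis[r] - 1;
    for (int j = 0; j < d; ++j) {
      const double x = M(r, j);
      if (x > E(v, j)) { E(v, j) = x; Amat(v, j) = (int)(r + 1); }
    }
  }
  return List::create(_["E"] = E, _["Amat"] = Amat);
}

// [[Rcpp::export]]
arma::mat maxpool_backward_cpp(const arma::mat& dE, const IntegerMatrix& Amat,
                               const int n_contrib) {
  const int d = dE.n_cols;
  const int n_vis = dE.n_rows;
  arma::mat dM(n_contrib, d, arma::fill::zeros);
  for (int v = 0; v < n_vis; ++v)
    for (int j = 0; j < d; ++j)
      dM(Amat(v, j) - 1, j) += dE(v, j);
  return dM;
}
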