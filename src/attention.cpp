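// Multi-head self-attention over a batch of variable-length sequences
// packed as rows of Q/K/V (column-major N x d). Each sequence is a
// contiguous row block; attention never crosses blocks. The forward pass
// returns the context matrix plus the flattened attention distributions
// (block-major, head within block) needed by the backward pass. Masked
// (causal) positions carry exactly zero attention weight, so the backward
// pass needs no mask: the zero entries of P annihilate their gradients.
//
// Blocks are short (tens of positions) and the head width small, so the
// kernels use plain loops over strided column-major data rather than BLAS
// calls, avoiding per-block temporaries.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List mha_forward_cpp(const NumericMatrix& Q, const NumericMatrix& K,
                     const NumericMatrix& V,
                     const IntegerVector& starts, const IntegerVector& lens,
                     const int H, const bool causal) {
  const int N = Q.nrow(), d = Q.ncol();
  const int dh = d / H;
  if (dh > 256) stop("head width above 256 unsupported");
  const double inv_sdh = 1.0 / std::sqrt((double)dh);
  NumericMatrix Ctx(N, d);
  const double *Qp = &Q[0], *Kp = &K[0], *Vp = &V[0];
  double* Cp = &Ctx[0];
  R_xlen_t tot = 0;
  int Lmax = 0;
  for (int b = 0; b < starts.size(); ++b) {
    tot += (R_xlen_t)lens[b] * lens[b] * H;
    if (lens[b] > Lmax) Lmax = lens[b];
  }
  NumericVector Pstore(tot);
  double* ps = &Pstore[0];
  std::vector<double> S((size_t)Lmax * Lmax);
  // contiguous per-block-head copies (L x dh, row-major by position) so the
  // inner products walk consecutive memory
  std::vector<double> Qb((size_t)Lmax * dh), Kb((size_t)Lmax * dh), Vb((size_t)Lmax * dh);
  R_xlen_t off = 0;
  for (int b = 0; b < starts.size(); ++b) {
    const int s = starts[b] - 1;   // 1-based from R
    const int L = lens[b];
    for (int h = 0; h < H; ++h) {
      const R_xlen_t c0 = (R_xlen_t)h * dh * N + s;  // offset of (s, h*dh)
      for (int c = 0; c < dh; ++c)
        for (int i = 0; i < L; ++i) {
          Qb[(size_t)i * dh + c] = Qp[c0 + (R_xlen_t)c * N + i];
          Kb[(size_t)i * dh + c] = Kp[c0 + (R_xlen_t)c * N + i];
          Vb[(size_t)i * dh + c] = Vp[c0 + (R_xlen_t)c * N + i];
        }
      // scores S[i + j*L] = <Q_i, K_j> / sqrt(dh)
      for (int j = 0; j < L; ++j) {
        const double* k = &Kb[(size_t)j * dh];
        for (int i = 0; i < L; ++i) {
          if (causal && j > i) { S[i + (size_t)j * L] = 0.0; continue; }
          const double* q = &Qb[(size_t)i * dh];
          double acc = 0.0;
          for (int c = 0; c < dh; ++c) acc += q[c] * k[c];
          S[i + (size_t)j * L] = acc * inv_sdh;
        }
      }
      // row-wise softmax over allowed positions, written into Pstore
      double* P = ps + off;
      for (int i = 0; i < L; ++i) {
        const int jmax = causal ? i : (L - 1);
        double mx = S[i];
        for (int j = 1; j <= jmax; ++j) {
          const double v = S[i + (size_t)j * L];
          if (v > mx) mx = v;
        }
        double sum = 0.0;
        for (int j = 0; j <= jmax; ++j) {
          const double e = std::exp(S[i + (size_t)j * L] - mx);
          P[i + (size_t)j * L] = e;
          sum += e;
        }
        const double inv = 1.0 / sum;
        for (int j = 0; j <= jmax; ++j) P[i + (size_t)j * L] *= inv;
        for (int j = jmax + 1; j < L; ++j) P[i + (size_t)j * L] = 0.0;
      }
      // context: Ctx[i, c] = sum_j P[i, j] V[j, c]
      for (int i = 0; i < L; ++i) {
        const int jmax = causal ? i : (L - 1);
        double acc[256];
        for (int c = 0; c < dh; ++c) acc[c] = 0.0;
        for (int j = 0; j <= jmax; ++j) {
          const double p = P[i + (size_t)j * L];
          const double* v = &Vb[(size_t)j * dh];
          for (int c = 0; c < dh; ++c) acc[c] += p * v[c];
        }
        for (int c = 0; c < dh; ++c) Cp[c0 + (R_xlen_t)c * N + i] = acc[c];
      }
      off += (R_xlen_t)L * L;
    }
  }
  return List::create(_["Ctx"] = Ctx, _["P"] = Pstore);
}

// [[Rcpp::export]]
List mha_backward_cpp(const NumericMatrix& dCtx, const NumericVector& Pstore,
                      const NumericMatrix& Q, const NumericMatrix& K,
                      const NumericMatrix& V,
                      const IntegerVector& starts, const IntegerVector& lens,
                      const int H) {
  const int N = Q.nrow(), d = Q.ncol();
  const int dh = d / H;
  if (dh > 256) stop("head width above 256 unsupported");
  const double inv_sdh = 1.0 / std::sqrt((double)dh);
  NumericMatrix dQ(N, d), dK(N, d), dV(N, d);
  const double *Qp = &Q[0], *Kp = &K[0], *Vp = &V[0], *dCp = &dCtx[0];
  double *dQp = &dQ[0], *dKp = &dK[0], *dVp = &dV[0];
  const double* ps = &Pstore[0];
  int Lmax = 0;
  for (int b = 0; b < starts.size(); ++b) if (lens[b] > Lmax) Lmax = lens[b];
  std::vector<double> dP((size_t)Lmax * Lmax), dS((size_t)Lmax * Lmax);
  std::vector<double> Qb((size_t)Lmax * dh), Kb((size_t)Lmax * dh),
    Vb((size_t)Lmax * dh), dCb((size_t)Lmax * dh);
  R_xlen_t off = 0;
  for (int b = 0; b < starts.size(); ++b) {
    const int s = starts[b] - 1;
    const int L = lens[b];
    for (int h = 0; h < H; ++h) {
      const R_xlen_t c0 = (R_xlen_t)h * dh * N + s;
      const double* P = ps + off;
      for (int c = 0; c < dh; ++c)
        for (int i = 0; i < L; ++i) {
          Qb[(size_t)i * dh + c] = Qp[c0 + (R_xlen_t)c * N + i];
          Kb[(size_t)i * dh + c] = Kp[c0 + (R_xlen_t)c * N + i];
          Vb[(size_t)i * dh + c] = Vp[c0 + (R_xlen_t)c * N + i];
          dCb[(size_t)i * dh + c] = dCp[c0 + (R_xlen_t)c * N + i];
        }
      // dP = dCtx_h V_h^T
      for (int j = 0; j < L; ++j) {
        const double* v = &Vb[(size_t)j * dh];
        for (int i = 0; i < L; ++i) {
          const double* dc = &dCb[(size_t)i * dh];
          double acc = 0.0;
          for (int c = 0; c < dh; ++c) acc += dc[c] * v[c];
          dP[i + (size_t)j * L] = acc;
        }
      }
      // dV_h = P^T dCtx_h
      for (int j = 0; j < L; ++j) {
        double acc[256];
        for (int c = 0; c < dh; ++c) acc[c] = 0.0;
        for (int i = 0; i < L; ++i) {
          const double p = P[i + (size_t)j * L];
          if (p == 0.0) continue;
          const double* dc = &dCb[(size_t)i * dh];
          for (int c = 0; c < dh; ++c) acc[c] += p * dc[c];
        }
        for (int c = 0; c < dh; ++c) dVp[c0 + (R_xlen_t)c * N + j] = acc[c];
      }
      // softmax backward: dS = P * (dP - rowsum(P * dP))
      for (int i = 0; i < L; ++i) {
        double rs = 0.0;
        for (int j = 0; j < L; ++j) rs += P[i + (size_t)j * L] * dP[i + (size_t)j * L];
        for (int j = 0; j < L; ++j) {
          const double p = P[i + (size_t)j * L];
          dS[i + (size_t)j * L] = p == 0.0 ? 0.0 : p * (dP[i + (size_t)j * L] - rs);
        }
      }
      // dQ_h = dS K_h / sqrt(dh); dK_h = dS^T Q_h / sqrt(dh)
      for (int i = 0; i < L; ++i) {
        double acc[256];
        for (int c = 0; c < dh; ++c) acc[c] = 0.0;
        for (int j = 0; j < L; ++j) {
          const double w = dS[i + (size_t)j * L];
          if (w == 0.0) continue;
          const double* k = &Kb[(size_t)j * dh];
          for (int c = 0; c < dh; ++c) acc[c] += w * k[c];
        }
        for (int c = 0; c < dh; ++c) dQp[c0 + (R_xlen_t)c * N + i] = acc[c] * inv_sdh;
      }
      for (int j = 0; j < L; ++j) {
        double acc[256];
        for (int c = 0; c < dh; ++c) acc[c] = 0.0;
        for (int i = 0; i < L; ++i) {
          const double w = dS[i + (size_t)j * L];
          if (w == 0.0) continue;
          const double* q = &Qb[(size_t)i * dh];
          for (int c = 0; c < dh; ++c) acc[c] += w * q[c];
        }
        for (int c = 0; c < dh; ++c) dKp[c0 + (R_xlen_t)c * N + j] = acc[c] * inv_sdh;
      }
      off += (R_xlen_t)L * L;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// Fused RMSprop update over a list of parameter arrays: one pass, two
// output allocations per parameter instead of R's elementwise temporaries.
// [[Rcpp::export]]
List rmsprop_update_cpp(const List& W, const List& G, const List& S,
                        const NumericVector& lr, const LogicalVector& decay_flag,
                        const double decay, const double eps, const double l2) {
  const int n = W.size();
  List Wout(n), Sout(n);
  for (int k = 0; k < n; ++k) {
    NumericVector w = W[k];
    NumericVector g = G[k];
    NumericVector s = S[k];
    const R_xlen_t m = w.size();
    NumericVector wn(m), sn(m);
    wn.attr("dim") = w.attr("dim");
    const bool dec = decay_flag[k] && l2 > 0;
    const double rate = lr[k];
    for (R_xlen_t i = 0; i < m; ++i) {
      double gi = g[i];
      if (dec) gi += 2.0 * l2 * w[i];
      const double si = decay * s[i] + (1.0 - decay) * gi * gi;
      sn[i] = si;
      wn[i] = w[i] - rate * gi / (std::sqrt(si) + eps);
    }
    Wout[k] = wn; Sout[k] = sn;
  }
  Wout.names() = W.names(); Sout.names() = S.names();
  return List::create(_["W"] = Wout, _["state"] = Sout);
}
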