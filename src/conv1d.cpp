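// Compiled kernels for the 1D CNN engine: kernel-3 length-preserving
// convolution (forward and backward) and the record-major flatten used
// between the convolutional stack and the dense head.
//
// Activations are (n * L) x C matrices, row (i * L + t) = sample t of
// record i (0-based). Weights arrive as Wcat = [Wm Wz Wp] (C_in x 3*C_out),
// one column block per kernel tap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& A, const arma::mat& Wcat,
                     const arma::rowvec& b, const int L) {
  const uword nL = A.n_rows;
  const uword n = nL / L;
  const uword Cout = Wcat.n_cols / 3;
  mat P = A * Wcat;
  mat Y = P.cols(Cout, 2 * Cout - 1);
  // tap t-1: P[:, 0:Cout) produced at row t-1 contributes to row t
  // tap t+1: P[:, 2Cout:3Cout) produced at row t+1 contributes to row t
  for (uword i = 0; i < n; ++i) {
    const uword lo = i * L, hi = i * L + L - 1;
    Y.rows(lo + 1, hi) += P.submat(lo, 0, hi - 1, Cout - 1);
    Y.rows(lo, hi - 1) += P.submat(lo + 1, 2 * Cout, hi, 3 * Cout - 1);
  }
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& A, const arma::mat& dY,
                      const arma::mat& Wcat, const int L,
                      const bool need_dA) {
  const uword nL = A.n_rows;
  const uword n = nL / L;
  const uword Cout = dY.n_cols;
  mat dYcat(nL, 3 * Cout, fill::zeros);
  dYcat.cols(Cout, 2 * Cout - 1) = dY;
  for (uword i = 0; i < n; ++i) {
    const uword lo = i * L, hi = i * L + L - 1;
    // dY aligned to the input row feeding each tap
    dYcat.submat(lo, 0, hi - 1, Cout - 1) = dY.rows(lo + 1, hi);
    dYcat.submat(lo + 1, 2 * Cout, hi, 3 * Cout - 1) = dY.rows(lo, hi - 1);
  }
  mat dWcat = A.t() * dYcat;
  rowvec db = sum(dY, 0);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dWcat") = dWcat, Rcpp::Named("db") = db);
  if (need_dA) {
    out["dA"] = mat(dYcat * Wcat.t());
  }
  return out;
}

// (n*L) x C -> n x (L*C): out(i, c*L + t) = A(i*L + t, c)
// [[Rcpp::export]]
arma::mat flatten_nlc_cpp(const arma::mat& A, const int n, const int L) {
  const uword C = A.n_cols;
  mat out(n, (uword)L * C);
  for (uword c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < L; ++t) {
        out(i, c * L + t) = A((uword)i * L + t, c);
      }
    }
  }
  return out;
}

// inverse of flatten_nlc_cpp
// [[Rcpp::export]]
arma::mat unflatten_nlc_cpp(const arma::mat& Xf, const int n, const int L) {
  const uword C = Xf.n_cols / L;
  mat out((uword)n * L, C);
  for (uword c = 0; c < C; ++c) {
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < L; ++t) {
        out((uword)i * L + t, c) = Xf(i, c * L + t);
      }
    }
  }
  return out;
}
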