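// 1-D convolution over multi-channel time series, "same" zero padding,
// stride 1.  Data layout: cube (time, channels, batch); weights as an
// im2col matrix (kernel*channels, filters) so the inner step is one GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// slice (T x C) -> patch matrix (T x K*C); column block k holds the input
// shifted by (k - K/2) samples, zero outside the record.
static mat im2col(const mat& Xs, const int K) {
  const int T = Xs.n_rows, C = Xs.n_cols;
  const int pad = K / 2;
  mat M(T, K * C, fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int off = k - pad;
    const int t0 = std::max(0, -off);
    const int t1 = std::min(T, T - off);
    if (t1 > t0)
      M.submat(t0, k * C, t1 - 1, (k + 1) * C - 1) = Xs.rows(t0 + off, t1 - 1 + off);
  }
  return M;
}

// [[Rcpp::export]]
arma::cube conv1d_forward(const arma::cube& X, const arma::mat& W,
                          const arma::rowvec& b, const int K) {
  const int T = X.n_rows, N = X.n_slices, F = W.n_cols;
  cube Y(T, F, N);
  for (int n = 0; n < N; ++n) {
    Y.slice(n) = im2col(X.slice(n), K) * W;
    Y.slice(n).each_row() += b;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::mat& W,
                           const arma::cube& dY, const int K) {
  const int T = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int pad = K / 2;
  mat dW(size(W), fill::zeros);
  rowvec db(W.n_cols, fill::zeros);
  cube dX(size(X), fill::zeros);
  for (int n = 0; n < N; ++n) {
    const mat M = im2col(X.slice(n), K);
    dW += M.t() * dY.slice(n);
    db += sum(dY.slice(n), 0);
    const mat dM = dY.slice(n) * W.t();
    for (int k = 0; k < K; ++k) {
      const int off = k - pad;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      if (t1 > t0)
        dX.slice(n).rows(t0 + off, t1 - 1 + off) +=
            dM.submat(t0, k * C, t1 - 1, (k + 1) * C - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
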