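// Compiled kernels for the causal dilated convolutions of the TCN.
// Layout: time series are C x T matrices (channels by time). A conv
// weight matrix W is C_out x (C_in * k); tap m (lag m*d samples)
// occupies columns [m*C_in, (m+1)*C_in).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat tcn_conv_fwd(const arma::mat& W, const arma::vec& b,
                       const arma::mat& X, int k, int d) {
  const int T = X.n_cols, cin = X.n_rows, cout = W.n_rows;
  mat Y(cout, T);
  Y.each_col() = b;
  for (int m = 0; m < k; ++m) {
    const int s = m * d;
    if (s >= T) break;
    Y.cols(s, T - 1) += W.cols(m * cin, (m + 1) * cin - 1) *
      X.cols(0, T - 1 - s);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List tcn_conv_bwd(const arma::mat& W, const arma::mat& X,
                        const arma::mat& dY, int k, int d) {
  const int T = X.n_cols, cin = X.n_rows, cout = W.n_rows;
  mat dW(cout, cin * k, fill::zeros);
  mat dX(cin, T, fill::zeros);
  vec db = sum(dY, 1);
  for (int m = 0; m < k; ++m) {
    const int s = m * d;
    if (s >= T) break;
    dW.cols(m * cin, (m + 1) * cin - 1) =
      dY.cols(s, T - 1) * X.cols(0, T - 1 - s).t();
    dX.cols(0, T - 1 - s) +=
      W.cols(m * cin, (m + 1) * cin - 1).t() * dY.cols(s, T - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

static const double INV_SQRT2 = 0.7071067811865475;
static const double INV_SQRT_2PI = 0.3989422804014327;

// exact GELU x * Phi(x); returns activation and Phi (cached for backward)
// [[Rcpp::export]]
Rcpp::List tcn_gelu_fwd(const arma::mat& A) {
  mat Phi(A.n_rows, A.n_cols), H(A.n_rows, A.n_cols);
  const double* a = A.memptr();
  double* ph = Phi.memptr();
  double* h = H.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) {
    ph[i] = 0.5 * (1.0 + std::erf(a[i] * INV_SQRT2));
    h[i] = a[i] * ph[i];
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Phi") = Phi);
}

// [[Rcpp::export]]
arma::mat tcn_gelu_bwd(const arma::mat& A, const arma::mat& Phi,
                       const arma::mat& dH) {
  mat dA(A.n_rows, A.n_cols);
  const double* a = A.memptr();
  const double* ph = Phi.memptr();
  const double* dh = dH.memptr();
  double* da = dA.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i)
    da[i] = dh[i] * (ph[i] + a[i] * std::exp(-0.5 * a[i] * a[i]) *
                     INV_SQRT_2PI);
  return dA;
}
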