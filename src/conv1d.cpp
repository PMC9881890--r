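// Dilated 1D convolution ("same" padding) forward and backward passes.
// Activations are cubes of shape (L, C, B): position x channel x sample.
// Weights are cubes of shape (K, Cin, Cout); K must be odd so that the
// zero-padding pad = dilation * (K - 1) / 2 keeps the output length at L.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".conv1dForward")]]
arma::cube conv1dForward(const arma::cube& X, const arma::cube& W,
                         const arma::vec& bias, const int dilation) {
  const uword L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const uword K = W.n_rows, Cout = W.n_slices;
  if (W.n_cols != Cin) Rcpp::stop("conv1d: channel mismatch");
  if (K % 2 == 0) Rcpp::stop("conv1d: kernel size must be odd");
  const uword pad = dilation * (K - 1) / 2;

  cube Y(L, Cout, B);
  // reorganise weights as K matrices of (Cin x Cout)
  std::vector<mat> Wk(K);
  for (uword k = 0; k < K; ++k) {
    mat wk(Cin, Cout);
    for (uword co = 0; co < Cout; ++co) wk.col(co) = W.slice(co).row(k).t();
    Wk[k] = wk;
  }
  mat Xp(L + 2 * pad, Cin);
  for (uword b = 0; b < B; ++b) {
    Xp.zeros();
    Xp.rows(pad, pad + L - 1) = X.slice(b);
    mat Yb(L, Cout, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      const uword off = k * dilation;
      Yb += Xp.rows(off, off + L - 1) * Wk[k];
    }
    Yb.each_row() += bias.t();
    Y.slice(b) = Yb;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1dBackward")]]
Rcpp::List conv1dBackward(const arma::cube& X, const arma::cube& W,
                          const arma::cube& dY, const int dilation) {
  const uword L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const uword K = W.n_rows, Cout = W.n_slices;
  const uword pad = dilation * (K - 1) / 2;

  std::vector<mat> Wk(K), dWk(K);
  for (uword k = 0; k < K; ++k) {
    mat wk(Cin, Cout);
    for (uword co = 0; co < Cout; ++co) wk.col(co) = W.slice(co).row(k).t();
    Wk[k] = wk;
    dWk[k] = mat(Cin, Cout, fill::zeros);
  }

  cube dX(L, Cin, B, fill::zeros);
  vec db(Cout, fill::zeros);
  mat Xp(L + 2 * pad, Cin), dXp(L + 2 * pad, Cin);
  for (uword b = 0; b < B; ++b) {
    Xp.zeros();
    Xp.rows(pad, pad + L - 1) = X.slice(b);
    dXp.zeros();
    const mat& dYb = dY.slice(b);
    for (uword k = 0; k < K; ++k) {
      const uword off = k * dilation;
      dXp.rows(off, off + L - 1) += dYb * Wk[k].t();
      dWk[k] += Xp.rows(off, off + L - 1).t() * dYb;
    }
    dX.slice(b) = dXp.rows(pad, pad + L - 1);
    db += sum(dYb, 0).t();
  }

  cube dW(K, Cin, Cout);
  for (uword co = 0; co < Cout; ++co)
    for (uword k = 0; k < K; ++k) dW.slice(co).row(k) = dWk[k].col(co).t();

  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
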