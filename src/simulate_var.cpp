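#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

//' VAR(p) recursion with pre-drawn innovations.
//'
//' coef is K x (K*p), lag blocks side by side (A_1 | A_2 | ... | A_p).
//' innov is K x n (already scaled by per-channel noise sd).  The recursion
//' starts from zeros; the caller discards the burn-in.
// [[Rcpp::export]]
arma::mat var_recurse(const arma::mat& coef, const arma::mat& innov, int p) {
  const arma::uword K = innov.n_rows;
  const arma::uword n = innov.n_cols;
  arma::mat y(K, n, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t) {
    arma::vec acc = innov.col(t);
    for (int r = 1; r <= p; ++r) {
      if (t >= static_cast<arma::uword>(r)) {
        acc += coef.cols((r - 1) * K, r * K - 1) * y.col(t - r);
      }
    }
    y.col(t) = acc;
  }
  return y;
}
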