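#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Solve the continuous-time Lyapunov equation A X + X A^T = C for X via the
// Schur / Bartels-Stewart method (LAPACK dgees + dtrsyl through Armadillo's
// Sylvester solver). Exact dense solve; A must have its spectrum in the open
// right half-plane for the stationary-covariance interpretation.
// [[Rcpp::export]]
arma::mat lyap_solve_cpp(const arma::mat& A, const arma::mat& C) {
  arma::mat X;
  const bool ok = arma::sylvester(X, A, A.t(), -C);
  if (!ok)
    Rcpp::stop("Lyapunov solve failed: coefficient matrix is singular or "
               "the Sylvester system is ill-conditioned");
  return X;
}
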