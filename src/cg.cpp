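// Jacobi-preconditioned conjugate gradient for the sparse SPD systems
// produced by the finite-volume electroquasistatic discretization.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export(name = ".cg_solve")]]
Rcpp::List cg_solve(const arma::sp_mat& A, const arma::vec& b,
                    double tol = 1e-8, int maxit = 10000) {
  const arma::uword n = A.n_rows;
  arma::vec x(n, arma::fill::zeros);
  arma::vec d = arma::vec(A.diag());
  for (arma::uword i = 0; i < n; ++i)
    if (d[i] <= 0) Rcpp::stop("non-positive diagonal in system matrix");
  arma::vec r = b;                      // r = b - A x, x = 0
  double bnorm = arma::norm(b);
  if (bnorm == 0.0)
    return Rcpp::List::create(Rcpp::Named("x") = x,
                              Rcpp::Named("relres") = 0.0,
                              Rcpp::Named("iters") = 0);
  arma::vec z = r / d;
  arma::vec p = z;
  double rz = arma::dot(r, z);
  double relres = arma::norm(r) / bnorm;
  int it = 0;
  while (relres > tol && it < maxit) {
    arma::vec Ap = A * p;
    double alpha = rz / arma::dot(p, Ap);
    x += alpha * p;
    r -= alpha * Ap;
    relres = arma::norm(r) / bnorm;
    z = r / d;
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
    ++it;
  }
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("relres") = relres,
                            Rcpp::Named("iters") = it);
}
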