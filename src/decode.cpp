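#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// L2-regularized logistic regression via iteratively reweighted least
// squares. The intercept is unpenalized. Returns coefficients for
// y = w'x + b with y01 == 1 the positive class.
static arma::vec irls_fit(const arma::mat& Z, const arma::vec& y01,
                          double lambda, int maxit, double tol) {
  const arma::uword p = Z.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::mat P(p, p, arma::fill::zeros);
  for (arma::uword j = 1; j < p; ++j) P(j, j) = lambda;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = Z * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec wgt = mu % (1.0 - mu);
    wgt.transform([](double x) { return x < 1e-10 ? 1e-10 : x; });
    arma::vec zz = eta + (y01 - mu) / wgt;
    arma::mat ZtW = Z.t() * arma::diagmat(wgt);
    arma::vec beta_new = arma::solve(ZtW * Z + P, ZtW * zz,
                                     arma::solve_opts::likely_sympd);
    const double delta = arma::norm(beta_new - beta, "inf");
    beta = beta_new;
    if (delta < tol) break;
  }
  return beta;
}

// [[Rcpp::export]]
List ridge_logistic_cpp(const arma::mat& X, const arma::vec& y01,
                        double lambda, int maxit = 50,
                        double tol = 1e-8) {
  arma::mat Z(X.n_rows, X.n_cols + 1);
  Z.col(0).ones();
  Z.cols(1, X.n_cols) = X;
  arma::vec beta = irls_fit(Z, y01, lambda, maxit, tol);
  return List::create(_["b"] = beta(0),
                      _["w"] = arma::vec(beta.subvec(1, X.n_cols)));
}

// Leave-one-trial-out discriminant scores: score[i] = w_(-i)'x_i + b_(-i)
// [[Rcpp::export]]
arma::vec loo_scores_cpp(const arma::mat& X, const arma::vec& y01,
                         double lambda, int maxit = 30,
                         double tol = 1e-7) {
  const arma::uword n = X.n_rows, D = X.n_cols;
  arma::mat Z(n, D + 1);
  Z.col(0).ones();
  Z.cols(1, D) = X;
  arma::vec out(n);
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec keep = arma::find(all != i);
    arma::vec beta = irls_fit(Z.rows(keep), y01.elem(keep), lambda,
                              maxit, tol);
    out(i) = arma::dot(Z.row(i).t(), beta);
  }
  return out;
}

// k-fold cross-validated scores (fold_id is 1-based per trial)
// [[Rcpp::export]]
arma::vec cv_scores_cpp(const arma::mat& X, const arma::vec& y01,
                        double lambda, const arma::uvec& fold_id,
                        int maxit = 30, double tol = 1e-7) {
  const arma::uword n = X.n_rows, D = X.n_cols;
  arma::mat Z(n, D + 1);
  Z.col(0).ones();
  Z.cols(1, D) = X;
  arma::vec out(n);
  const arma::uword K = fold_id.max();
  for (arma::uword k = 1; k <= K; ++k) {
    arma::uvec test = arma::find(fold_id == k);
    if (test.n_elem == 0) continue;
    arma::uvec train = arma::find(fold_id != k);
    arma::vec beta = irls_fit(Z.rows(train), y01.elem(train), lambda,
                              maxit, tol);
    out.elem(test) = Z.rows(test) * beta;
  }
  return out;
}
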