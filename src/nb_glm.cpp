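// Negative-binomial log-link GLM fitting via iteratively reweighted least
// squares, applied independently per feature. The NB variance is
// mu + alpha * mu^2 with a fixed, per-feature dispersion alpha; alpha = 0
// reduces to the Poisson model used for the initial dispersion estimate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_MAX = 30.0;  // exp(30) ~ 1e13, caps divergence of
                                     // means for degenerate (all-zero group)
                                     // features without aborting the fit

// One IRLS fit. Returns true when the fit converged; beta/se are filled with
// the final state either way (se may be NaN if the information matrix is
// singular).
static bool irls_one(const arma::vec& y, const arma::mat& X,
                     const arma::vec& offset, double alpha, double tol,
                     int maxit, arma::vec& beta, arma::vec& se, int& iters) {
  const arma::uword p = X.n_cols;
  arma::vec eta0 = arma::log(y + 0.5);
  beta.set_size(p);
  se.set_size(p);
  se.fill(arma::datum::nan);
  iters = 0;

  // initialise from an unweighted least-squares fit to log(y + 0.5)
  if (!arma::solve(beta, X, eta0 - offset)) return false;

  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = arma::clamp(X * beta + offset, -ETA_MAX, ETA_MAX);
    arma::vec mu = arma::exp(eta);
    arma::vec W = mu / (1.0 + alpha * mu);
    arma::vec z = (eta - offset) + (y - mu) / mu;
    arma::mat Xw = X.each_col() % W;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    if (!arma::solve(beta_new, XtWX, XtWz, arma::solve_opts::no_approx) ||
        !beta_new.is_finite()) {
      iters = it;
      return false;
    }
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    iters = it + 1;
    if (delta < tol) {
      conv = true;
      break;
    }
  }

  // standard errors from the Fisher information at the final estimate
  arma::vec eta = arma::clamp(X * beta + offset, -ETA_MAX, ETA_MAX);
  arma::vec mu = arma::exp(eta);
  arma::vec W = mu / (1.0 + alpha * mu);
  arma::mat Xw = X.each_col() % W;
  arma::mat XtWX = X.t() * Xw;
  arma::mat cov;
  if (!arma::inv_sympd(cov, XtWX)) {
    if (!arma::inv(cov, XtWX)) return false;
  }
  se = arma::sqrt(cov.diag());
  return conv;
}

// Fit one NB GLM per row of `counts`. `offset` is the per-sample log size
// factor, `alpha` the per-feature dispersion.
// [[Rcpp::export]]
List nb_glm_fit_matrix(const arma::mat& counts, const arma::mat& X,
                       const arma::vec& offset, const arma::vec& alpha,
                       double tol = 1e-8, int maxit = 100) {
  const arma::uword nfeat = counts.n_rows, p = X.n_cols;
  if (counts.n_cols != X.n_rows) stop("counts and design disagree on samples");
  if (offset.n_elem != X.n_rows) stop("offset length must match samples");
  if (alpha.n_elem != nfeat) stop("one dispersion per feature required");

  arma::mat beta(nfeat, p), se(nfeat, p);
  LogicalVector converged(nfeat);
  IntegerVector iterations(nfeat);

  for (arma::uword i = 0; i < nfeat; ++i) {
    arma::vec b, s;
    int it = 0;
    bool ok = irls_one(counts.row(i).t(), X, offset, alpha(i), tol, maxit, b, s, it);
    beta.row(i) = b.t();
    se.row(i) = s.t();
    converged(i) = ok && s.is_finite();
    iterations(i) = it;
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["converged"] = converged,
                      _["iterations"] = iterations);
}

// Method-of-moments dispersion per feature: fit a Poisson log-linear model
// with the given offsets, then
//   alpha_hat = max( sum(((y - mu)^2 - mu) / mu^2) / (n - p), alpha_min ).
// [[Rcpp::export]]
NumericVector moment_dispersion_matrix(const arma::mat& counts,
                                       const arma::mat& X,
                                       const arma::vec& offset,
                                       double alpha_min = 1e-8,
                                       double tol = 1e-8, int maxit = 100) {
  const arma::uword nfeat = counts.n_rows;
  const double n = static_cast<double>(X.n_rows);
  const double p = static_cast<double>(X.n_cols);
  if (n <= p) stop("need more samples than design columns");
  NumericVector out(nfeat);

  for (arma::uword i = 0; i < nfeat; ++i) {
    arma::vec y = counts.row(i).t();
    arma::vec b, s;
    int it = 0;
    irls_one(y, X, offset, 0.0, tol, maxit, b, s, it);
    arma::vec mu = arma::exp(arma::clamp(X * b + offset, -ETA_MAX, ETA_MAX));
    double acc = arma::accu((arma::square(y - mu) - mu) / arma::square(mu));
    double a = acc / (n - p);
    out[i] = (std::isfinite(a) && a > alpha_min) ? a : alpha_min;
  }
  return out;
}
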