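// Negative-binomial GLM engine: IRLS at fixed dispersion and Cox-Reid
// adjusted profile likelihood estimation of the dispersion, per feature.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <functional>
using namespace Rcpp;

// One IRLS fit of y ~ NB(mu = exp(X b + off), dispersion alpha).
// Working weights mu/(1+alpha*mu) are the Fisher weights for the log link.
static bool nb_irls(const arma::vec& y, const arma::mat& X,
                    const arma::vec& off, double alpha,
                    arma::vec& beta, arma::mat& XtWX, double& ll,
                    int maxit, double tol) {
  const int n = y.n_elem;
  arma::vec mu = y + 0.5;
  arma::vec eta = arma::log(mu);
  beta.zeros(X.n_cols);
  double crit_old = R_PosInf;
  bool conv = false;
  const double size = 1.0 / alpha;

  for (int it = 0; it < maxit; ++it) {
    arma::vec w = mu / (1.0 + alpha * mu);
    arma::vec z = (eta - off) + (y - mu) / mu;
    arma::mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    arma::vec rhs = Xw.t() * z;
    arma::vec beta_new;
    if (!arma::solve(beta_new, XtWX, rhs,
                     arma::solve_opts::likely_sympd + arma::solve_opts::no_approx)) {
      return false;
    }
    beta = beta_new;
    eta = arma::clamp(X * beta + off, -30.0, 30.0);
    mu = arma::exp(eta);
    double crit = 0.0;
    for (int i = 0; i < n; ++i) crit += R::dnbinom_mu(y(i), size, mu(i), 1);
    if (std::fabs(crit - crit_old) < tol * (std::fabs(crit) + 0.1)) {
      conv = true;
      break;
    }
    crit_old = crit;
  }
  ll = 0.0;
  for (int i = 0; i < n; ++i) ll += R::dnbinom_mu(y(i), size, mu(i), 1);
  arma::vec w = mu / (1.0 + alpha * mu);
  XtWX = X.t() * (X.each_col() % w);
  return conv;
}

// Cox-Reid adjusted profile log-likelihood at a given dispersion.
static double cr_apl(const arma::vec& y, const arma::mat& X,
                     const arma::vec& off, double alpha) {
  arma::vec beta;
  arma::mat XtWX;
  double ll;
  nb_irls(y, X, off, alpha, beta, XtWX, ll, 50, 1e-6);
  double val, sign;
  if (!arma::log_det(val, sign, XtWX) || sign <= 0) return -1e300;
  return ll - 0.5 * val;
}

static double golden_max(const std::function<double(double)>& f,
                         double a, double b, int iters) {
  const double gr = 0.6180339887498949;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = f(c), fd = f(d);
  for (int i = 0; i < iters; ++i) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a); fc = f(c);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a); fd = f(d);
    }
  }
  return 0.5 * (a + b);
}

// Per-feature Cox-Reid dispersion MLE on the log scale.
// [[Rcpp::export]]
NumericVector nb_alpha_mle(const NumericMatrix& Ym, const NumericMatrix& Xm,
                           const NumericVector& offv,
                           double alpha_min, double alpha_max) {
  const arma::mat Y(const_cast<double*>(Ym.begin()), Ym.nrow(), Ym.ncol(), false);
  const arma::mat X(const_cast<double*>(Xm.begin()), Xm.nrow(), Xm.ncol(), false);
  const arma::vec off(const_cast<double*>(offv.begin()), offv.size(), false);
  const double la = std::log(alpha_min), lb = std::log(alpha_max);
  NumericVector alpha(Ym.nrow(), NA_REAL);
  for (int i = 0; i < Ym.nrow(); ++i) {
    arma::vec y = Y.row(i).t();
    if (arma::accu(y) <= 0) continue;
    auto f = [&](double la_) { return cr_apl(y, X, off, std::exp(la_)); };
    alpha[i] = std::exp(golden_max(f, la, lb, 35));
  }
  return alpha;
}

// Wald fit at fixed per-feature dispersions; returns the coefficient of
// interest, its standard error and convergence per feature.
// [[Rcpp::export]]
List nb_wald_fit(const NumericMatrix& Ym, const NumericMatrix& Xm,
                 const NumericVector& offv, const NumericVector& alphas,
                 int coef, int maxit = 100, double tol = 1e-8) {
  const arma::mat Y(const_cast<double*>(Ym.begin()), Ym.nrow(), Ym.ncol(), false);
  const arma::mat X(const_cast<double*>(Xm.begin()), Xm.nrow(), Xm.ncol(), false);
  const arma::vec off(const_cast<double*>(offv.begin()), offv.size(), false);
  const int nb = Ym.nrow(), p = Xm.ncol(), j = coef - 1;
  NumericVector beta(nb, NA_REAL), se(nb, NA_REAL);
  LogicalVector conv(nb, false);
  for (int i = 0; i < nb; ++i) {
    arma::vec y = Y.row(i).t();
    if (arma::accu(y) <= 0 || !R_finite(alphas[i])) continue;
    arma::vec b;
    arma::mat XtWX;
    double ll;
    bool ok = nb_irls(y, X, off, alphas[i], b, XtWX, ll, maxit, tol);
    arma::mat cov;
    if (!arma::inv_sympd(cov, XtWX)) continue;
    beta[i] = b(j);
    se[i] = std::sqrt(cov(j, j));
    conv[i] = ok;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["converged"] = conv,
                      _["p"] = p);
}
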