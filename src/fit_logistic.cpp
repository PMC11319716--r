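// Logistic-regression IRLS core used by the pattern scan.
//
// Two entry points share one Newton/IRLS engine with a fixed convergence
// contract (relative log-likelihood change < tol, max `maxit` iterations),
// quasi-separation flagged when any coefficient exceeds `sep` on the
// log-odds scale, and rank-deficient designs flagged degenerate instead of
// silently falling back to a pseudoinverse.
//
// .fit_logistic_cpp fits an arbitrary subject-level design.
//
// .fit_designs_cpp exploits the scan's structure: every covariate of every
// catalog pattern is constant within the 9 joint-genotype cells, so the
// Bernoulli likelihood depends on the data only through per-cell subject and
// case counts. Fitting the binomial-aggregated 9-row representation yields
// the identical maximum likelihood, log-likelihood and Wald standard errors
// at a cost independent of the subject count, which is what makes scans of
// 10^5 pairs tractable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct FitResult {
  arma::vec beta;
  arma::vec se;
  double logLik;
  int iter;
  bool converged;
  bool separated;
  bool degenerate;
};

// Weighted (binomial-count) IRLS. `X` has one row per covariate class,
// `ntot` the subjects and `ycnt` the cases per class. Subject-level fits are
// the special case ntot == 1, ycnt == y.
FitResult irls(const arma::mat& X, const arma::vec& ntot,
               const arma::vec& ycnt, int maxit, double tol, double sep) {
  FitResult res;
  const arma::uword k = X.n_cols;
  res.beta = arma::vec(k, arma::fill::value(NA_REAL));
  res.se = arma::vec(k, arma::fill::value(NA_REAL));
  res.logLik = NA_REAL;
  res.iter = 0;
  res.converged = false;
  res.separated = false;
  res.degenerate = false;

  const arma::uvec obs = arma::find(ntot > 0);
  const arma::mat Xo = X.rows(obs);
  const arma::vec no = ntot.elem(obs);
  const arma::vec yo = ycnt.elem(obs);

  if (arma::rank(Xo) < k) {
    res.degenerate = true;
    return res;
  }

  arma::vec beta(k, arma::fill::zeros);
  arma::vec eta(Xo.n_rows, arma::fill::zeros);

  auto loglik = [&](const arma::vec& e) {
    double ll = 0.0;
    for (arma::uword i = 0; i < e.n_elem; ++i) {
      const double l1pe = (e(i) > 30.0) ? e(i) : std::log1p(std::exp(e(i)));
      ll += yo(i) * e(i) - no(i) * l1pe;
    }
    return ll;
  };

  double ll_old = loglik(eta);
  double ll = ll_old;

  for (int it = 1; it <= maxit; ++it) {
    res.iter = it;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = no % arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
    arma::vec z = eta + (yo - no % mu) / w;
    arma::mat Xw = Xo.each_col() % w;
    arma::mat XtWX = Xo.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    const bool ok = arma::solve(beta_new, XtWX, XtWz,
                                arma::solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) {
      res.degenerate = true;
      return res;
    }
    beta = beta_new;
    eta = Xo * beta;
    ll = loglik(eta);
    if (arma::abs(beta).max() > sep) {
      // coefficients diverged along a (quasi-)separating direction
      res.separated = true;
      break;
    }
    if (std::abs(ll - ll_old) < tol * (std::abs(ll) + 0.1)) {
      res.converged = true;
      break;
    }
    ll_old = ll;
  }

  res.beta = beta;
  res.logLik = ll;

  // observed-information standard errors at the final estimate
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec w = no % arma::clamp(mu % (1.0 - mu), 1e-10, 0.25);
  arma::mat XtWX = Xo.t() * (Xo.each_col() % w);
  arma::mat cov;
  if (arma::inv_sympd(cov, XtWX)) {
    res.se = arma::sqrt(cov.diag());
  } else {
    res.degenerate = true;
  }
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".fit_logistic_cpp")]]
List fit_logistic_cpp(const arma::mat& X, const arma::vec& y, int maxit,
                      double tol, double sep) {
  arma::vec ones(X.n_rows, arma::fill::ones);
  FitResult r = irls(X, ones, y, maxit, tol, sep);
  return List::create(
      _["coefficients"] = NumericVector(r.beta.begin(), r.beta.end()),
      _["se"] = NumericVector(r.se.begin(), r.se.end()),
      _["logLik"] = r.logLik, _["iter"] = r.iter, _["converged"] = r.converged,
      _["separated"] = r.separated, _["degenerate"] = r.degenerate);
}

// Batched grouped entry point for the pair scan. `grid` holds every coded
// column evaluated on the 9 joint-genotype cells (ordered by 3*g1 + g2);
// `ncell`/`ycell` are per-cell subject and case counts; each element of
// `designs` is a 1-based column-index vector into `grid` (an implicit
// intercept is prepended). Returns one row per design with the
// interaction-term (last-column) Wald ingredients.
// [[Rcpp::export(name = ".fit_designs_cpp")]]
DataFrame fit_designs_cpp(const arma::mat& grid, const arma::vec& ncell,
                          const arma::vec& ycell, const List& designs,
                          int maxit, double tol, double sep) {
  const int m = designs.size();
  NumericVector logLik(m), b_int(m), se_int(m);
  IntegerVector kvec(m), iter(m);
  LogicalVector converged(m), separated(m), degenerate(m);

  for (int j = 0; j < m; ++j) {
    IntegerVector idx = designs[j];
    arma::mat X(grid.n_rows, idx.size() + 1);
    X.col(0).ones();
    for (int c = 0; c < idx.size(); ++c) X.col(c + 1) = grid.col(idx[c] - 1);
    FitResult r = irls(X, ncell, ycell, maxit, tol, sep);
    kvec[j] = X.n_cols;
    logLik[j] = r.logLik;
    iter[j] = r.iter;
    converged[j] = r.converged;
    separated[j] = r.separated;
    degenerate[j] = r.degenerate;
    if (r.degenerate) {
      b_int[j] = NA_REAL;
      se_int[j] = NA_REAL;
    } else {
      b_int[j] = r.beta(X.n_cols - 1);
      se_int[j] = r.se(X.n_cols - 1);
    }
  }
  return DataFrame::create(
      _["k"] = kvec, _["logLik"] = logLik, _["b_int"] = b_int,
      _["se_int"] = se_int, _["iter"] = iter, _["converged"] = converged,
      _["separated"] = separated, _["degenerate"] = degenerate);
}
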