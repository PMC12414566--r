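// EM core for latent-class trajectory models without random effects
// (diagonal within-class covariance: GBTM and LCGA families).  The mixed
// (growth mixture) families are handled by the vectorized R path; this
// kernel exists because the parametric bootstrap refits thousands of
// small diagonal-covariance models.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// residual structures: 0 FIXED, 1 FREE_OVER_TIME, 2 FREE_OVER_CLASSES,
// 3 FREE_BOTH
// [[Rcpp::export]]
Rcpp::List em_gbtm_cpp(const arma::mat& Y0, const arma::mat& obs,
                       const Rcpp::List& X_list, arma::vec pi0,
                       const Rcpp::List& beta0, arma::mat theta,
                       int resid_structure, int max_iter, double tol,
                       double var_floor) {
  const uword N = Y0.n_rows, T = Y0.n_cols;
  const uword K = pi0.n_elem;
  std::vector<mat> X(K);
  std::vector<vec> beta(K);
  for (uword k = 0; k < K; ++k) {
    X[k] = Rcpp::as<mat>(X_list[k]);
    beta[k] = Rcpp::as<vec>(beta0[k]);
  }
  vec pi = pi0;
  vec n_obs_i = sum(obs, 1);
  const double LOG2PI = std::log(2.0 * datum::pi);
  mat P(N, K, fill::zeros);
  std::vector<double> trace;
  bool converged = false;
  bool floor_active = false;
  double ll_old = -datum::inf, ll = 0.0;

  for (int iter = 0; iter < max_iter; ++iter) {
    // E step
    mat logf(N, K);
    for (uword k = 0; k < K; ++k) {
      rowvec th = theta.row(k);
      vec mu = X[k] * beta[k];
      mat R = Y0 - repmat(mu.t(), N, 1);
      R %= obs;
      vec q1(N, fill::zeros), ldet(N, fill::zeros);
      for (uword t = 0; t < T; ++t) {
        q1 += square(R.col(t)) / th(t);
        ldet += obs.col(t) * std::log(th(t));
      }
      logf.col(k) = -0.5 * (n_obs_i * LOG2PI + ldet + q1);
    }
    mat lp = logf;
    for (uword k = 0; k < K; ++k) lp.col(k) += std::log(std::max(pi(k), 1e-300));
    vec mx = max(lp, 1);
    vec lse = mx + log(sum(exp(lp.each_col() - mx), 1));
    ll = accu(lse);
    trace.push_back(ll);
    P = exp(lp.each_col() - lse);
    if (std::isfinite(ll_old) &&
        std::abs(ll - ll_old) < tol * (std::abs(ll_old) + 1.0)) {
      converged = true;
      break;
    }
    ll_old = ll;
    // CM steps
    pi = mean(P, 0).t();
    pi = clamp(pi, 1e-12, datum::inf);
    pi /= accu(pi);
    mat num(K, T, fill::zeros), den(K, T, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      rowvec th = theta.row(k);
      vec w = P.col(k);
      rowvec a_t = sum(obs.each_col() % w, 0);   // sum_i w_i obs_it
      rowvec b_t = sum(Y0.each_col() % w, 0);    // sum_i w_i y_it
      mat XtWX(X[k].n_cols, X[k].n_cols, fill::zeros);
      vec XtWy(X[k].n_cols, fill::zeros);
      for (uword t = 0; t < T; ++t) {
        XtWX += (a_t(t) / th(t)) * (X[k].row(t).t() * X[k].row(t));
        XtWy += (b_t(t) / th(t)) * X[k].row(t).t();
      }
      vec bnew;
      bool ok = solve(bnew, XtWX, XtWy, solve_opts::no_approx);
      if (ok) beta[k] = bnew;
      vec mu = X[k] * beta[k];
      mat E2 = Y0 - repmat(mu.t(), N, 1);
      E2 = square(E2) % obs;
      num.row(k) = sum(E2.each_col() % w, 0);
      den.row(k) = a_t;
    }
    mat theta_new(K, T);
    switch (resid_structure) {
      case 0: theta_new.fill(accu(num) / std::max(accu(den), 1e-12)); break;
      case 1: {
        rowvec tn = sum(num, 0) / clamp(sum(den, 0), 1e-12, datum::inf);
        theta_new = repmat(tn, K, 1);
        break;
      }
      case 2: {
        vec tk = sum(num, 1) / clamp(sum(den, 1), 1e-12, datum::inf);
        theta_new = repmat(tk, 1, T);
        break;
      }
      default: theta_new = num / clamp(den, 1e-12, datum::inf);
    }
    for (uword k = 0; k < K; ++k) {
      for (uword t = 0; t < T; ++t) {
        if (!std::isfinite(theta_new(k, t)) || theta_new(k, t) < var_floor) {
          floor_active = true;
          theta_new(k, t) = std::max(theta(k, t), var_floor);
        }
      }
    }
    theta = theta_new;
  }
  Rcpp::List beta_out(K);
  for (uword k = 0; k < K; ++k) beta_out[k] = beta[k];
  return Rcpp::List::create(
      Rcpp::Named("pi") = pi,
      Rcpp::Named("beta") = beta_out,
      Rcpp::Named("theta") = theta,
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = (int)trace.size(),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("posteriors") = P,
      Rcpp::Named("floor_active") = floor_active);
}
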