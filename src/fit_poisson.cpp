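// Newton solver for the ridge-penalized Poisson log-likelihood with
// exponential link. The objective
//   sum_t [ y_t * eta_t - exp(eta_t) ] - lambda * sum_j penal_j * w_j^2
// (eta = b + X w) is concave, so Newton steps with step-halving converge to
// the unique maximum. The intercept is carried as an extra unpenalized
// column appended internally.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List cpp_fit_poisson_ridge(const arma::mat& X, const arma::vec& y,
                                 const arma::vec& penalized, double lambda,
                                 arma::vec init, double tol_grad,
                                 int max_iter) {
  const uword p = X.n_cols;
  vec pen(p + 1, fill::zeros);
  pen.head(p) = penalized * lambda;

  vec w = init;  // length p + 1, intercept last
  if (w.n_elem != p + 1) {
    w.zeros(p + 1);
    double mb = mean(y);
    w(p) = std::log(std::max(mb, 1e-8));
  }

  auto eta_of = [&](const vec& wv) { return vec(X * wv.head(p) + wv(p)); };
  auto obj_of = [&](const vec& wv, const vec& eta) {
    // exp(eta) can overflow during line search; treat as -inf objective
    vec mu = exp(eta);
    if (!mu.is_finite()) return -datum::inf;
    return dot(y, eta) - accu(mu) - dot(pen, square(wv));
  };

  vec eta = eta_of(w);
  double obj = obj_of(w, eta);
  double gnorm = datum::inf;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    vec mu = exp(eta);
    vec resid = y - mu;
    vec g(p + 1);
    g.head(p) = X.t() * resid - 2.0 * (pen.head(p) % w.head(p));
    g(p) = accu(resid);
    gnorm = norm(g, "inf");
    if (gnorm < tol_grad) { converged = true; break; }

    // Hessian: [X 1]' diag(mu) [X 1] + 2 diag(pen)
    mat Xw = X.each_col() % sqrt(mu);
    mat H(p + 1, p + 1);
    H.submat(0, 0, p - 1, p - 1) = Xw.t() * Xw;
    vec xm = X.t() * mu;
    H.submat(0, p, p - 1, p) = xm;
    H.submat(p, 0, p, p - 1) = xm.t();
    H(p, p) = accu(mu);
    H.diag() += 2.0 * pen;
    H.diag() += 1e-10;  // guard exact singularity on degenerate designs

    vec step;
    bool ok = solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { solve(step, H, g); }

    double t = 1.0;
    vec w_new, eta_new;
    double obj_new = -datum::inf;
    bool improved = false;
    for (int ls = 0; ls < 60; ++ls) {
      w_new = w + t * step;
      eta_new = eta_of(w_new);
      obj_new = obj_of(w_new, eta_new);
      if (obj_new > obj - 1e-12) { improved = true; break; }
      t *= 0.5;
    }
    if (!improved) break;  // no admissible step: report final gradient below
    w = w_new; eta = eta_new; obj = obj_new;
  }
  if (!converged) {
    // final gradient for the diagnostic
    vec mu = exp(eta);
    vec g(p + 1);
    g.head(p) = X.t() * (y - mu) - 2.0 * (pen.head(p) % w.head(p));
    g(p) = accu(y - mu);
    gnorm = norm(g, "inf");
    converged = gnorm < tol_grad;
  }

  return Rcpp::List::create(
      Rcpp::Named("coef") = w.head(p), Rcpp::Named("intercept") = w(p),
      Rcpp::Named("converged") = converged, Rcpp::Named("grad_norm") = gnorm,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("objective") = obj);
}
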