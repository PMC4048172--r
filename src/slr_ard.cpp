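#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Sparse Bayesian logistic regression with automatic relevance determination.
//
// Each weight w_i carries a zero-mean Gaussian prior with precision alpha_i.
// The fit alternates (a) Newton-Raphson to the MAP weights at fixed alpha,
// (b) a Laplace approximation of the posterior covariance S = H^{-1},
// (c) MacKay evidence updates alpha_i <- gamma_i / w_i^2 with
//     gamma_i = 1 - alpha_i S_ii,
// (d) pruning of features whose precision exceeds the prune threshold --
// until the weight vector stabilizes.  The bias has a fixed broad prior and
// is never pruned; pruned features never re-enter.
//
// Two Newton/covariance code paths: a direct (m x m) path when the active
// set is small, and a Woodbury path costing O(m n^2) when m > n (the usual
// situation in the first sweeps over a whole-mask voxel set).

static const double MU_EPS = 1e-10;

namespace {

struct ArdWork {
  vec eta, mu, Bv, resid, g, wnew, wtry, gam, t1;
  mat XaB, H, S, L, V, Vs, M, T;
  void size_direct(uword n, uword m) {
    eta.set_size(n); mu.set_size(n); Bv.set_size(n); resid.set_size(n);
    g.set_size(m); wnew.set_size(m); wtry.set_size(m); gam.set_size(m);
    t1.set_size(m);
    XaB.set_size(n, m); H.set_size(m, m); S.set_size(m, m);
    L.set_size(m, m);
  }
};

// mu and Bv at eta = Xa * w, written into preallocated buffers
inline void logistic_moments(const mat& Xa, const vec& w, ArdWork& wk) {
  wk.eta = Xa * w;
  const uword n = wk.eta.n_elem;
  for (uword i = 0; i < n; ++i) {
    double m = 1.0 / (1.0 + std::exp(-wk.eta(i)));
    if (m < MU_EPS) m = MU_EPS;
    if (m > 1.0 - MU_EPS) m = 1.0 - MU_EPS;
    wk.mu(i) = m;
    wk.Bv(i) = m * (1.0 - m);
  }
}

inline double penalized_loglik(const mat& Xa, const vec& y,
                               const vec& alpha, const vec& w, ArdWork& wk) {
  wk.eta = Xa * w;
  double ll = 0.0;
  for (uword i = 0; i < wk.eta.n_elem; ++i) {
    double m = 1.0 / (1.0 + std::exp(-wk.eta(i)));
    if (m < MU_EPS) m = MU_EPS;
    if (m > 1.0 - MU_EPS) m = 1.0 - MU_EPS;
    ll += y(i) * std::log(m) + (1.0 - y(i)) * std::log(1.0 - m);
  }
  for (uword j = 0; j < w.n_elem; ++j) ll -= 0.5 * alpha(j) * w(j) * w(j);
  return ll;
}

// One Newton step; returns the proposed weights in wk.wnew.
inline void newton_direction(const mat& Xa, const vec& y, const vec& alpha,
                             const vec& w, ArdWork& wk) {
  const uword n = Xa.n_rows, m = Xa.n_cols;
  logistic_moments(Xa, w, wk);
  if (m > n) {  // Woodbury: solve in the n-dimensional dual
    vec b = sqrt(wk.Bv);
    wk.V = Xa.each_col() % b;
    wk.Vs = wk.V.each_row() / alpha.t();
    wk.M = wk.Vs * wk.V.t();
    wk.M.diag() += 1.0;
    wk.L = chol(wk.M, "lower");
    vec bz = b % wk.eta + (y - wk.mu) / b;
    vec t2 = solve(trimatu(wk.L.t()), solve(trimatl(wk.L), bz));
    wk.wnew = wk.Vs.t() * t2;
  } else {
    const uword m = Xa.n_cols;
    wk.XaB = Xa.each_col() % wk.Bv;
    wk.H = Xa.t() * wk.XaB;
    for (uword j = 0; j < m; ++j) wk.H(j, j) += alpha(j);
    wk.resid = y - wk.mu;
    wk.g = Xa.t() * wk.resid;
    for (uword j = 0; j < m; ++j) wk.g(j) -= alpha(j) * w(j);
    // Newton step via Cholesky; triangular solves done in place
    if (!chol(wk.L, wk.H, "lower"))
      wk.L = chol(wk.H + 1e-8 * eye(m, m), "lower");
    wk.wnew = wk.g;
    int mm = static_cast<int>(m), one = 1;
    F77_CALL(dtrsv)("L", "N", "N", &mm, wk.L.memptr(), &mm,
                    wk.wnew.memptr(), &one FCONE FCONE FCONE);
    F77_CALL(dtrsv)("L", "T", "N", &mm, wk.L.memptr(), &mm,
                    wk.wnew.memptr(), &one FCONE FCONE FCONE);
    wk.wnew += w;
  }
}

// Newton-Raphson to the MAP at fixed alpha, with step halving.
inline void newton_map(const mat& Xa, const vec& y, const vec& alpha,
                       vec& w, int max_newton, double tol, ArdWork& wk) {
  for (int it = 0; it < max_newton; ++it) {
    newton_direction(Xa, y, alpha, w, wk);
    double ll0 = penalized_loglik(Xa, y, alpha, w, wk);
    wk.wtry = wk.wnew;
    double t = 1.0;
    for (int h = 0; h < 12; ++h) {
      if (penalized_loglik(Xa, y, alpha, wk.wtry, wk) >= ll0 - 1e-12) break;
      t *= 0.5;
      wk.wtry = w + t * (wk.wnew - w);
    }
    double delta = norm(wk.wtry - w, "inf") / (norm(w, "inf") + 1e-12);
    w = wk.wtry;
    if (delta < tol) break;
  }
}

// gamma_i = 1 - alpha_i S_ii (features only), S the Laplace covariance at w.
inline void effective_gammas(const mat& Xa, const vec& alpha, const vec& w,
                             ArdWork& wk) {
  const uword n = Xa.n_rows, m = Xa.n_cols;
  logistic_moments(Xa, w, wk);  // refresh mu, Bv at the converged w
  if (m > n) {
    vec b = sqrt(wk.Bv);
    wk.V = Xa.each_col() % b;
    wk.Vs = wk.V.each_row() / alpha.t();
    wk.M = wk.Vs * wk.V.t();
    wk.M.diag() += 1.0;
    wk.L = chol(wk.M, "lower");
    wk.T = solve(trimatl(wk.L), wk.V);
    // gamma_i = alpha_i * q_i = ||L^{-1} u_i||^2 / alpha_i (stable for
    // diverging alpha; avoids the 1/alpha - S_ii cancellation)
    wk.gam = sum(square(wk.T), 0).t() / alpha;
  } else {
    const uword mm = Xa.n_cols;
    wk.XaB = Xa.each_col() % wk.Bv;
    wk.H = Xa.t() * wk.XaB;
    for (uword j = 0; j < mm; ++j) wk.H(j, j) += alpha(j);
    wk.S = inv_sympd(wk.H);
    for (uword j = 0; j < mm; ++j) wk.gam(j) = 1.0 - alpha(j) * wk.S(j, j);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List slr_ard_fit_cpp(const arma::mat& X, const arma::vec& y,
                           double alpha_init, double prune_threshold,
                           int max_iter, double tol, double bias_precision,
                           int max_newton, double newton_tol) {
  const uword n = X.n_rows, p = X.n_cols;
  uvec active = regspace<uvec>(0, (p > 0) ? p - 1 : 0);
  if (p == 0) active.reset();

  mat Xa(n, p + 1);
  if (p > 0) Xa.head_cols(p) = X;
  Xa.col(p).ones();
  vec alpha(p + 1, fill::value(alpha_init));
  alpha(p) = bias_precision;
  vec w(p + 1, fill::zeros);

  ArdWork wk;
  wk.size_direct(n, Xa.n_cols);
  vec w_full(p + 1, fill::zeros), w_full_prev(p + 1, fill::zeros);
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    const uword m = active.n_elem;  // features currently in the model
    newton_map(Xa, y, alpha, w, max_newton, newton_tol, wk);

    if (m > 0) {
      effective_gammas(Xa, alpha, w, wk);
      // A feature whose precision is rising while its weight has fallen
      // below 0.1% of the largest weight is on a monotone geometric path
      // to the prune threshold and no longer influences the model; prune
      // it now rather than iterating the evidence update to 1e8. The
      // early sweeps (iter < 5) are exempt so the initial ranking of
      // correlated features is not short-circuited.
      double wmax = std::abs(w(m));  // bias
      for (uword i = 0; i < m; ++i)
        wmax = std::max(wmax, std::abs(w(i)));
      const double w_floor = std::max(1e-3 * wmax, 1e-6);
      uvec keep(m);
      uword k = 0;
      for (uword i = 0; i < m; ++i) {
        double w2 = w(i) * w(i);
        double a_new = (w2 > 0 && std::isfinite(wk.gam(i)))
                           ? wk.gam(i) / w2 : datum::inf;
        bool vanishing = iter >= 5 && a_new > alpha(i) &&
                         std::abs(w(i)) < w_floor;
        if (a_new <= prune_threshold && !vanishing) {
          alpha(k) = std::max(a_new, 1e-10);
          keep(k++) = i;
        }
      }
      if (k < m) {  // shrink the active model in place
        keep.resize(k);
        active = active(keep);
        uvec cols = join_cols(keep, uvec{m});  // surviving cols + bias
        Xa = Xa.cols(cols);
        vec w2v = w(cols);
        w = w2v;
        alpha(k) = bias_precision;
        alpha.resize(k + 1);
        wk.size_direct(n, Xa.n_cols);
      }
    }

    // per-coordinate relative change keeps the loop alive while any
    // surviving weight is still moving
    w_full.zeros();
    for (uword i = 0; i < active.n_elem; ++i) w_full(active(i)) = w(i);
    w_full(p) = w(active.n_elem);
    double delta = 0.0;
    for (uword j = 0; j <= p; ++j) {
      double d = std::abs(w_full(j) - w_full_prev(j)) /
                 (std::abs(w_full_prev(j)) + 1e-12);
      if (w_full(j) == 0.0 && w_full_prev(j) == 0.0) d = 0.0;
      if (d > delta) delta = d;
    }
    w_full_prev = w_full;
    if (delta < tol) { converged = true; break; }
  }

  const uword m = active.n_elem;
  return Rcpp::List::create(
      Rcpp::Named("retained") = Rcpp::IntegerVector(active.begin(), active.end()),
      Rcpp::Named("w") = Rcpp::NumericVector(w.begin(), w.begin() + m),
      Rcpp::Named("bias") = w(m),
      Rcpp::Named("alpha") = Rcpp::NumericVector(alpha.begin(), alpha.begin() + m),
      Rcpp::Named("n_iter") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged);
}

// MAP weights at fixed prior precisions (no ARD update) -- the inner
// subproblem, exposed so it can be checked against brute-force oracles.
// [[Rcpp::export]]
Rcpp::List slr_map_fixed_alpha_cpp(const arma::mat& X, const arma::vec& y,
                                   const arma::vec& alpha_feat,
                                   double bias_precision,
                                   int max_newton, double newton_tol) {
  const uword n = X.n_rows, p = X.n_cols;
  mat Xa(n, p + 1);
  Xa.head_cols(p) = X;
  Xa.col(p).ones();
  vec alpha(p + 1);
  alpha.head(p) = alpha_feat;
  alpha(p) = bias_precision;
  vec w(p + 1, fill::zeros);
  ArdWork wk;
  wk.size_direct(n, p + 1);
  newton_map(Xa, y, alpha, w, max_newton, newton_tol, wk);
  return Rcpp::List::create(
      Rcpp::Named("w") = Rcpp::NumericVector(w.begin(), w.begin() + p),
      Rcpp::Named("bias") = w(p));
}
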