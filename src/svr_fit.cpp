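#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Linear epsilon-insensitive support vector regression, solved in the
// primal:
//
//   min_w  0.5 * ||w||^2  +  C * sum_i max(0, |y_i - x_i' w| - eps)
//
// The objective is strictly convex in w (unique minimizer) and w is only
// p-dimensional (cell types + intercept), so a damped Newton method on a
// Huber-smoothed loss with continuation mu -> 0 reaches the exact
// solution in a few dozen iterations, deterministically. Smoothing: for
// slack s = max(|r| - eps, 0), the loss is s^2/(2 mu) when s < mu and
// s - mu/2 otherwise; mu is driven from the data scale down to 1e-8 of it.
// An intercept, if wanted, is an extra all-ones column of X (L2-penalized
// like any coefficient).

static double svr_objective(const arma::mat& X, const arma::vec& y,
                            const arma::vec& w, double C, double eps,
                            double mu) {
  arma::vec s = arma::abs(y - X * w) - eps;
  s.transform([](double v) { return v > 0.0 ? v : 0.0; });
  double loss = 0.0;
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    loss += (s[i] < mu) ? s[i] * s[i] / (2.0 * mu) : s[i] - mu / 2.0;
  }
  return 0.5 * arma::dot(w, w) + C * loss;
}

// [[Rcpp::export]]
List svr_primal_fit(const arma::mat& X, const arma::vec& y,
                    double C, double eps, double tol, int max_iter) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n) stop("length(y) must equal nrow(X)");
  if (C <= 0.0) stop("C must be positive");
  if (eps < 0.0) stop("eps must be non-negative");

  arma::vec w(p, arma::fill::zeros);
  double mu0 = arma::abs(y).max();
  if (mu0 <= 0.0) mu0 = 1.0;               // all-zero y: w = 0 is optimal
  const double mu_final = 1e-8 * mu0;
  const double gtol = tol * (1.0 + C);
  double mu = mu0;
  int total_it = 0;
  bool converged = false;

  while (true) {
    converged = false;
    for (int it = 0; it < 200 && total_it < max_iter; ++it, ++total_it) {
      arma::vec r = y - X * w;
      arma::vec psi(n);                     // d loss / d r, per observation
      arma::uvec active(n);
      arma::uword na = 0;
      for (arma::uword i = 0; i < n; ++i) {
        double a = std::fabs(r[i]) - eps;
        if (a <= 0.0) { psi[i] = 0.0; continue; }
        double sgn = (r[i] > 0.0) ? 1.0 : -1.0;
        if (a < mu) { psi[i] = sgn * a / mu; active[na++] = i; }
        else psi[i] = sgn;
      }
      arma::vec g = w - C * (X.t() * psi);
      if (arma::abs(g).max() < gtol) { converged = true; break; }
      arma::mat H = arma::eye(p, p);
      if (na > 0) {
        arma::mat Xa = X.rows(active.head(na));
        H += (C / mu) * (Xa.t() * Xa);
      }
      arma::vec d = -arma::solve(H, g, arma::solve_opts::likely_sympd);
      double f0 = svr_objective(X, y, w, C, eps, mu);
      double gd = arma::dot(g, d);
      double step = 1.0;
      while (step > 1e-12 &&
             svr_objective(X, y, w + step * d, C, eps, mu) >
               f0 + 1e-4 * step * gd) {
        step *= 0.5;
      }
      if (step <= 1e-12) {                  // Armijo stall: at the numerical
        converged = true;                   // floor for this mu, no further
        break;                              // progress is possible
      }
      w += step * d;
      double f1 = svr_objective(X, y, w, C, eps, mu);
      if (f0 - f1 < 1e-12 * (std::fabs(f0) + 1.0)) {
        converged = true;                   // objective at its numerical floor
        break;
      }
    }
    if (mu <= mu_final || total_it >= max_iter) break;
    mu = std::max(mu * 0.1, mu_final);
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = total_it,
                      _["converged"] = converged);
}
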