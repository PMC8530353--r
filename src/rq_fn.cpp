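// Frisch-Newton interior-point solver for the quantile-regression LP
// (Mehrotra predictor-corrector on the bounded-dual formulation:
//  min c'a  s.t.  X'a = (1-tau) X'1,  0 <= a <= 1,  with c = -y;
//  the regression coefficients are the negated equality multipliers).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double step_bound(const vec& v, const vec& dv) {
  double b = 1e20;
  for (uword i = 0; i < v.n_elem; ++i) {
    if (dv(i) < 0) {
      double cand = -v(i) / dv(i);
      if (cand < b) b = cand;
    }
  }
  return b;
}

// [[Rcpp::export(name = ".rq_fn_cpp")]]
Rcpp::List rq_fn_cpp(const arma::mat& X, const arma::vec& y, double tau,
                     int maxit = 100, double eps = 1e-9) {
  const uword n = X.n_rows;
  const double beta_step = 0.9995;

  vec cc = -y;
  vec x(n, fill::value(1.0 - tau));
  vec b_eq = X.t() * x;
  vec s = 1.0 - x;

  vec yv;
  bool ok = solve(yv, X.t() * X, X.t() * cc, solve_opts::likely_sympd);
  if (!ok) Rcpp::stop("singular design in quantile-regression solver");
  vec r = cc - X * yv;
  r.transform([](double v) { return v == 0.0 ? 0.001 : v; });
  vec z = r % (r > 0);
  vec w = z - r;

  double gap = dot(cc, x) - dot(yv, b_eq) + accu(w);
  int it = 0;
  vec q(n);
  mat Xq(n, X.n_cols);
  while (gap > eps * (1.0 + std::abs(dot(cc, x))) && it < maxit) {
    ++it;
    for (uword i = 0; i < n; ++i) {
      double d = z(i) / x(i) + w(i) / s(i);
      q(i) = 1.0 / (d > 1e-12 ? d : 1e-12);
    }
    r = z - w;
    {
      vec sq = sqrt(q);
      for (uword j = 0; j < X.n_cols; ++j) Xq.col(j) = X.col(j) % sq;
    }
    mat M = Xq.t() * Xq;
    vec dy;
    if (!solve(dy, M, X.t() * (q % r),
               solve_opts::likely_sympd + solve_opts::no_approx)) break;
    vec dx = q % (X * dy - r);
    vec ds = -dx;
    vec dz = -z % (1.0 + dx / x);
    vec dw = -w % (1.0 + ds / s);
    double fp = std::min(beta_step * std::min(step_bound(x, dx),
                                              step_bound(s, ds)), 1.0);
    double fd = std::min(beta_step * std::min(step_bound(w, dw),
                                              step_bound(z, dz)), 1.0);
    if (std::min(fp, fd) < 1.0) {
      // Mehrotra corrector
      double mu = dot(z, x) + dot(w, s);
      double g = dot(z + fd * dz, x + fp * dx) +
                 dot(w + fd * dw, s + fp * ds);
      mu = mu * std::pow(g / mu, 3) / (2.0 * n);
      vec dxdz = dx % dz;
      vec dsdw = ds % dw;
      vec xinv = 1.0 / x;
      vec sinv = 1.0 / s;
      vec xi = mu * (xinv - sinv);
      if (!solve(dy, M, X.t() * (q % (r + dxdz - dsdw - xi)),
                 solve_opts::likely_sympd + solve_opts::no_approx)) break;
      dx = q % (X * dy + xi - r - dxdz + dsdw);
      ds = -dx;
      dz = mu * xinv - z - xinv % z % dx - dxdz;
      dw = mu * sinv - w - sinv % w % ds - dsdw;
      fp = std::min(beta_step * std::min(step_bound(x, dx),
                                         step_bound(s, ds)), 1.0);
      fd = std::min(beta_step * std::min(step_bound(w, dw),
                                         step_bound(z, dz)), 1.0);
    }
    x += fp * dx;
    s += fp * ds;
    yv += fd * dy;
    w += fd * dw;
    z += fd * dz;
    gap = dot(cc, x) - dot(yv, b_eq) + accu(w);
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = -yv,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("gap") = gap,
      Rcpp::Named("converged") =
          gap <= eps * (1.0 + std::abs(dot(cc, x))));
}
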