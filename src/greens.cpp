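#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Modified Bessel K0 via the Abramowitz & Stegun polynomial fits
// (9.8.5/9.8.6 together with the I0 fit 9.8.1); absolute error < 2e-8,
// ample for envelope interpolation where the same kernel defines both the
// linear system and its evaluation.
static double bessk0(double x) {
  if (x <= 2.0) {
    double t = x / 3.75;
    t *= t;
    double i0 = 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
                t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
    double y = x * x / 4.0;
    return -std::log(x / 2.0) * i0 + (-0.57721566 + y * (0.42278420 +
           y * (0.23069756 + y * (0.03488590 + y * (0.00262698 +
           y * (0.00010750 + y * 0.00000740))))));
  }
  double y = 2.0 / x;
  return std::exp(-x) / std::sqrt(x) * (1.25331414 + y * (-0.07832358 +
         y * (0.02189568 + y * (-0.01062446 + y * (0.00587872 +
         y * (-0.00251540 + y * 0.00053208))))));
}

// Radial Green's function of the 2D spline-in-tension operator.
// p = 0: biharmonic limit r^2 (log r - 1).
// p > 0: Wessel-Becker form K0(p r) + log(p r), finite at r = 0 with
//        limit log(2) - Euler gamma.
static inline double gt_kernel(double r, double p) {
  if (p <= 0.0) {
    if (r <= 0.0) return 0.0;
    return r * r * (std::log(r) - 1.0);
  }
  if (r <= 0.0) return 0.11593151565841245;
  double x = p * r;
  return bessk0(x) + std::log(x);
}

// [[Rcpp::export(name = ".gt_fit")]]
Rcpp::List gt_fit(const arma::vec& px, const arma::vec& py, const arma::vec& v,
                  double p, int nx, int ny, double ridge) {
  const arma::uword n = px.n_elem;
  const arma::uword dim = n + 3;

  // Radial system augmented with an affine part under moment conditions,
  // so affine data are reproduced exactly at every tension.
  arma::mat A(dim, dim, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = i; j < n; ++j) {
      double r = std::hypot(px(i) - px(j), py(i) - py(j));
      double g = gt_kernel(r, p);
      A(i, j) = g;
      A(j, i) = g;
    }
    A(i, i) += ridge;
    A(i, n) = A(n, i) = 1.0;
    A(i, n + 1) = A(n + 1, i) = px(i);
    A(i, n + 2) = A(n + 2, i) = py(i);
  }

  arma::vec b(dim, arma::fill::zeros);
  b.head(n) = v;

  arma::vec sol;
  bool ok = arma::solve(sol, A, b, arma::solve_opts::no_approx);
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("resid") = R_PosInf);
  }

  // Residual at the data sites (ridge contribution removed so this measures
  // interpolation exactness of the returned surface, not of the solve).
  double resid = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double s = arma::dot(A.row(i).t(), sol) - ridge * sol(i) - v(i);
    resid = std::max(resid, std::abs(s));
  }

  const double a0 = sol(n), a1 = sol(n + 1), a2 = sol(n + 2);
  arma::mat S(nx, ny);
  for (int gy = 0; gy < ny; ++gy) {
    double yy = gy + 1.0;
    for (int gx = 0; gx < nx; ++gx) {
      double xx = gx + 1.0;
      double s = a0 + a1 * xx + a2 * yy;
      for (arma::uword k = 0; k < n; ++k) {
        s += sol(k) * gt_kernel(std::hypot(xx - px(k), yy - py(k)), p);
      }
      S(gx, gy) = s;
    }
  }

  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("surface") = S,
                            Rcpp::Named("resid") = resid);
}

// [[Rcpp::export(name = ".gt_kernel_values")]]
arma::vec gt_kernel_values(const arma::vec& r, double p) {
  arma::vec out(r.n_elem);
  for (arma::uword i = 0; i < r.n_elem; ++i) out(i) = gt_kernel(r(i), p);
  return out;
}
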