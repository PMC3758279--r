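#include <Rcpp.h>
using namespace Rcpp;

// Penalized weighted least squares by cyclic coordinate descent with an
// active-set strategy: one full sweep, then sweeps over the nonzero set
// until converged, repeated until a full sweep changes nothing beyond
// tol.  The intercept is unpenalized.  Operates on standardized
// predictors; called from the IRLS loop of fit_l1_path().

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_wls_cpp")]]
List cd_wls_cpp(NumericMatrix Xs, NumericVector w, NumericVector z,
                double b0, NumericVector beta0_in, double lambda,
                double tol, int max_sweeps) {
  const int n = Xs.nrow();
  const int p = Xs.ncol();
  NumericVector beta = clone(beta0_in);
  std::vector<double> v(p);           // curvature: sum(w x^2) / n
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &Xs(0, j);
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
    v[j] = s / n;
  }
  // residual r = z - b0 - Xs beta
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = z[i] - b0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double* xj = &Xs(0, j);
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * beta[j];
    }
  }
  int sweeps = 0;
  auto update_j = [&](int j) -> double {
    if (v[j] <= 0.0) return 0.0;
    const double* xj = &Xs(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * r[i];
    double rho = s / n + v[j] * beta[j];
    double bn = soft(rho, lambda) / v[j];
    double d = bn - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      beta[j] = bn;
    }
    return std::fabs(d);
  };
  auto update_intercept = [&]() -> double {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * r[i];
    double d = s / wsum;
    if (d != 0.0) {
      b0 += d;
      for (int i = 0; i < n; ++i) r[i] -= d;
    }
    return std::fabs(d);
  };
  while (sweeps < max_sweeps) {
    ++sweeps;
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) maxd = std::max(maxd, update_j(j));
    maxd = std::max(maxd, update_intercept());
    if (maxd < tol) break;
    // iterate the active set to convergence
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (!active.empty() && sweeps < max_sweeps) {
      ++sweeps;
      double da = 0.0;
      for (int j : active) da = std::max(da, update_j(j));
      da = std::max(da, update_intercept());
      if (da < tol) break;
    }
  }
  return List::create(_["b0"] = b0, _["beta"] = beta,
                      _["sweeps"] = sweeps);
}
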