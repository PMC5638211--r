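#include <Rcpp.h>
using namespace Rcpp;

// Node-wise lasso on the Gram (covariance) matrix Gamma.
//
// For each response column j, minimizes over g (with g[j] fixed at 0)
//   0.5 * g' Gamma g - Gamma[,j]' g + lambda * ||g||_1
// by cyclic coordinate descent with soft-thresholding, using Gamma's
// diagonal as curvature. Solving directly on Gamma makes subsampled
// refits cheap: no design matrix is ever formed.
//
// G is modified in place (warm start across a lambda path); returns the
// number of unconverged columns, and writes per-column sweep counts into
// `sweeps`.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_neighborhood")]]
List cd_neighborhood(NumericMatrix Gamma, double lambda,
                     NumericMatrix Ginit, double tol, int max_iter) {
  const int d = Gamma.nrow();
  NumericMatrix G = clone(Ginit);
  IntegerVector sweeps(d);
  LogicalVector converged(d);
  std::vector<double> v(d); // v = Gamma %*% g for current column

  for (int j = 0; j < d; ++j) {
    // initialize v from warm-start coefficients
    std::fill(v.begin(), v.end(), 0.0);
    for (int k = 0; k < d; ++k) {
      double gk = G(k, j);
      if (gk != 0.0) {
        const double* col = &Gamma(0, k);
        for (int m = 0; m < d; ++m) v[m] += col[m] * gk;
      }
    }
    bool ok = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (int k = 0; k < d; ++k) {
        if (k == j) continue;
        double akk = Gamma(k, k);
        if (akk <= 0.0) continue; // zero-variance protein: coefficient stays 0
        double gk = G(k, j);
        // partial residual: Gamma[k,j] - sum_{m != k} Gamma[k,m] g[m]
        double r = Gamma(k, j) - (v[k] - akk * gk);
        double gnew = soft(r, lambda) / akk;
        double delta = gnew - gk;
        if (delta != 0.0) {
          G(k, j) = gnew;
          const double* col = &Gamma(0, k);
          for (int m = 0; m < d; ++m) v[m] += col[m] * delta;
          double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) { ok = true; ++it; break; }
    }
    sweeps[j] = it;
    converged[j] = ok;
    G(j, j) = 0.0;
  }
  return List::create(_["coefficients"] = G,
                      _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
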