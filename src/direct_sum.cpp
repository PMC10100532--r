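#include <Rcpp.h>
#include <cmath>

// O(N^2) collocation Coulomb sum over grid nodes; the self (j == i)
// interaction uses the equivalent-sphere value passed from R so the
// convention lives in exactly one place on the R side.
// [[Rcpp::export]]
Rcpp::NumericVector direct_sum_potential(Rcpp::NumericVector rho,
                                         Rcpp::IntegerVector shape,
                                         Rcpp::NumericVector ax,
                                         Rcpp::NumericVector ay,
                                         Rcpp::NumericVector az,
                                         double h, double self_term) {
  const int n1 = shape[0], n2 = shape[1], n3 = shape[2];
  const int n = n1 * n2 * n3;
  const double h3 = h * h * h;
  Rcpp::NumericVector V(n);
  std::vector<double> x(n), y(n), z(n);
  {
    int idx = 0;
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i, ++idx) {
          x[idx] = ax[i];
          y[idx] = ay[j];
          z[idx] = az[k];
        }
  }
  for (int i = 0; i < n; ++i) {
    double acc = rho[i] * self_term;
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      acc += rho[j] / std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    V[i] = acc * h3;
  }
  return V;
}
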