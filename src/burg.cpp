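#include <Rcpp.h>
using namespace Rcpp;

// Burg (maximum-entropy) AR estimation, one column of `x` per series.
// Minimizes the summed forward+backward prediction error at each order;
// reflection coefficients are bounded by |k| <= 1 by construction.
// Returns coefficients in the autoregressive convention
//   x[t] = phi_1 x[t-1] + ... + phi_p x[t-p] + e[t]
// (same sign convention as stats::ar.burg) and the final prediction-error
// variance.
// [[Rcpp::export]]
List burg_ar_cpp(NumericMatrix x, int order) {
  const int n = x.nrow();
  const int m = x.ncol();
  if (order >= n) stop("model order must be smaller than the series length");
  NumericMatrix phi(order, m);
  NumericVector var_pred(m);

  std::vector<double> f(n), b(n), a(order), a_prev(order);
  for (int s = 0; s < m; ++s) {
    double e0 = 0.0;
    for (int i = 0; i < n; ++i) {
      f[i] = x(i, s);
      b[i] = x(i, s);
      e0 += f[i] * f[i];
    }
    double E = e0 / n;
    if (E < 1e-30) {            // constant/zero segment: flat spectrum guard
      for (int j = 0; j < order; ++j) phi(j, s) = 0.0;
      var_pred[s] = 1e-30;
      continue;
    }
    std::fill(a.begin(), a.end(), 0.0);
    for (int p = 1; p <= order; ++p) {
      double num = 0.0, den = 0.0;
      for (int i = p; i < n; ++i) {
        num += f[i] * b[i - 1];
        den += f[i] * f[i] + b[i - 1] * b[i - 1];
      }
      double k = (den > 0.0) ? (-2.0 * num / den) : 0.0;
      // update AR polynomial: a_j <- a_j + k * a_{p-j}
      for (int j = 0; j < p - 1; ++j) a_prev[j] = a[j];
      for (int j = 0; j < p - 1; ++j) a[j] = a_prev[j] + k * a_prev[p - 2 - j];
      a[p - 1] = k;
      // update prediction errors (backward pass, descending index)
      for (int i = n - 1; i >= p; --i) {
        double fi = f[i];
        f[i] = fi + k * b[i - 1];
        b[i] = b[i - 1] + k * fi;
      }
      E *= (1.0 - k * k);
    }
    for (int j = 0; j < order; ++j) phi(j, s) = -a[j];
    var_pred[s] = (E > 1e-30) ? E : 1e-30;
  }
  return List::create(_["phi"] = phi, _["var_pred"] = var_pred);
}
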