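#include <Rcpp.h>
using namespace Rcpp;

// Count template matches for sample entropy with lagged embedding.
// Templates u_i = [x(i), x(i+tau), ..., x(i+(d-1)tau)] for d = m and m+1,
// both over the common index range i = 0 .. n - m*tau - 1 (0-based), so the
// (m+1)-point template is always defined. B = pairs (i < j) with Chebyshev
// distance <= r at d = m; A = same at d = m + 1. Self-matches excluded.
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampenCounts(NumericVector x, int m, int tau, double r) {
  const int n = x.size();
  const int nt = n - m * tau;  // number of templates with m+1 points
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int d = 0; d < m; ++d) {
        double diff = x[i + d * tau] - x[j + d * tau];
        if (diff < 0) diff = -diff;
        if (diff > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double diff = x[i + m * tau] - x[j + m * tau];
      if (diff < 0) diff = -diff;
      if (diff <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
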