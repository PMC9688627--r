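#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy (Richman & Moorman).
// Templates of length m start at i = 0..n-m-1 so every template also has
// an (m+1)-th point; B counts pairs matching for m points under the
// Chebyshev norm within r, A those also matching at m+1. Self-matches
// are excluded (pairs i < j only).
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampenCounts(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::abs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Higuchi curve lengths L(k), k = 1..kmax, averaged over offsets with
// the standard normalisation (n-1) / (floor((n-m)/k) * k).
// [[Rcpp::export(name = ".higuchiLk")]]
NumericVector higuchiLk(NumericVector x, int kmax) {
  int n = x.size();
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 1; m <= k; ++m) {
      int nm = (n - m) / k;            // points in the subsampled curve
      if (nm < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nm; ++i)
        s += std::abs(x[m + i * k - 1] - x[m + (i - 1) * k - 1]);
      Lk += s * (double)(n - 1) / ((double)nm * k) / k;
    }
    L[k - 1] = Lk / k;
  }
  return L;
}
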