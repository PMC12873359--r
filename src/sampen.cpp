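#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for Sample Entropy, Richman-Moorman convention:
// the N - m templates x[i..i+m-1], i = 0..N-m-1, are compared pairwise
// (i < j, self-matches excluded) under the Chebyshev distance with
// tolerance r (inclusive). B counts m-point matches, A counts those pairs
// whose (m+1)-th points also match; every template has a defined extension
// because i + m <= N - 1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (r <= 0) stop("r must be > 0");
  if (n < m + 2) stop("sequence too short: need length >= m + 2");
  double A = 0.0, B = 0.0;
  const int nt = n - m;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(Named("A") = A, Named("B") = B);
}
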