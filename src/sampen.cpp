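#include <Rcpp.h>
using namespace Rcpp;

// Sample-entropy template match counts (Richman-Moorman convention):
// templates X_i = (x[i], x[i+tau], ..., x[i+(m-1)tau]); both the
// length-m and length-(m+1) counts run over the same index range
// i = 0 .. N - m*tau - 1 so every length-m template considered also has
// an (m+1)-th point. Counts are over ordered pairs i != j under the
// Chebyshev (max-coordinate) distance with tolerance r.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r, int tau) {
  const int n = x.size();
  const int nt = n - m * tau;  // number of usable template origins
  if (nt < 2) stop("series too short for the requested m and tau");
  const double *p = x.begin();
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    const double *pi = p + i;
    for (int j = i + 1; j < nt; ++j) {
      const double *pj = p + j;
      bool match = true;
      for (int k = 0, off = 0; k < m; ++k, off += tau) {
        double d = pi[off] - pj[off];
        if (d < 0) d = -d;
        if (d > r) { match = false; break; }
      }
      if (match) {
        B += 2.0;  // ordered pairs: (i,j) and (j,i)
        double d = pi[m * tau] - pj[m * tau];
        if (d < 0) d = -d;
        if (d <= r) A += 2.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
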