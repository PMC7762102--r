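#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR difference equation,
// a[0]*y[n] = b[0]*x[n] + z1[n-1], zero initial conditions.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a,
                         NumericVector x) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  const double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  std::vector<double> z(nz, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
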