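#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with optional initial state.
// a[0] must be 1; zi has length max(len(a), len(b)) - 1.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             Nullable<NumericVector> zi = R_NilValue) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    for (int i = 0; i < nz && i < z0.size(); ++i) z[i] = z0[i];
  }
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
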