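#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed, single
// forward pass. sos rows are (b0, b1, b2, a0, a1, a2) with a0 == 1
// after normalization.
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double a0 = sos(s, 3);
    const double b0 = sos(s, 0) / a0, b1 = sos(s, 1) / a0, b2 = sos(s, 2) / a0;
    const double a1 = sos(s, 4) / a0, a2 = sos(s, 5) / a0;
    double z1 = 0.0, z2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
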