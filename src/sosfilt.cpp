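#include <Rcpp.h>
using namespace Rcpp;

// One forward pass of a biquad cascade (direct form II transposed) with
// steady-state initial conditions: each section starts in the state it
// would occupy after an infinitely long constant input equal to the first
// sample, so a constant input produces its steady-state output from sample
// one with no start-up transient.
// [[Rcpp::export]]
NumericVector sosfilt_ss(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow(), n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double a0 = sos(s, 3);
    double b0 = sos(s, 0) / a0, b1 = sos(s, 1) / a0, b2 = sos(s, 2) / a0;
    double a1 = sos(s, 4) / a0, a2 = sos(s, 5) / a0;
    double u = n > 0 ? y[0] : 0.0;
    double h = (b0 + b1 + b2) / (1.0 + a1 + a2); // DC gain of the section
    double z1 = (h - b0) * u;
    double z2 = (b2 - a2 * h) * u;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
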