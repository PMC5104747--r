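#include <Rcpp.h>
using namespace Rcpp;

// Direct-form I two-pole/two-zero filter with per-sample coefficients
// (already normalized by a0). Used for the time-varying resonant and
// band-pass sections of the sound models.
// [[Rcpp::export]]
NumericVector biquad_tv(NumericVector x, NumericVector b0, NumericVector b1,
                        NumericVector b2, NumericVector a1,
                        NumericVector a2) {
  R_xlen_t n = x.size();
  if (b0.size() != n || b1.size() != n || b2.size() != n || a1.size() != n ||
      a2.size() != n)
    stop("coefficient vectors must match the signal length");
  NumericVector y(n);
  double x1 = 0.0, x2 = 0.0, y1 = 0.0, y2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double yi = b0[i] * x[i] + b1[i] * x1 + b2[i] * x2 - a1[i] * y1 -
                a2[i] * y2;
    y[i] = yi;
    x2 = x1;
    x1 = x[i];
    y2 = y1;
    y1 = yi;
  }
  return y;
}
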