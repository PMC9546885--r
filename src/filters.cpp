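#include <Rcpp.h>
using namespace Rcpp;

// Direct-form IIR filter y[i] = (sum_j b[j] x[i-j] - sum_k a[k] y[i-k]) / a[0]
// with zero initial conditions; one pass of the forward-backward pair.
// Raw pointers keep the inner loops free of SEXP accessor overhead.
// [[Rcpp::export]]
NumericVector cpp_filter_iir(NumericVector bv, NumericVector av,
                             NumericVector xv) {
  const int n = xv.size(), nb = bv.size(), na = av.size();
  NumericVector yv(n);
  const double *b = bv.begin(), *a = av.begin(), *x = xv.begin();
  double *y = yv.begin();
  const double a0 = a[0];
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const int jmax = std::min(i, nb - 1);
    for (int j = 0; j <= jmax; ++j) acc += b[j] * x[i - j];
    const int kmax = std::min(i, na - 1);
    for (int k = 1; k <= kmax; ++k) acc -= a[k] * y[i - k];
    y[i] = acc / a0;
  }
  return yv;
}
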