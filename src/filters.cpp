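#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase IIR filtering of matrix columns: odd-reflection padding of
// `padlen` samples at each end, forward pass, backward pass, unpad.
// Coefficients are direct-form (b, a) with a[0] == 1. The caller removes
// the column means beforehand so the zero initial state is exact at DC.
// [[Rcpp::export(name = ".iir_filtfilt")]]
NumericMatrix iir_filtfilt(NumericVector b, NumericVector a,
                           NumericMatrix X, int padlen) {
  const int n = X.nrow(), p = X.ncol();
  const int nb = b.size(), na = a.size();
  const int m = n + 2 * padlen;
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  NumericMatrix out(n, p);
  std::vector<double> x(m), y(m);

  for (int j = 0; j < p; ++j) {
    // odd reflection: 2*x[0] - x[k] at the top, likewise at the bottom
    for (int k = 0; k < padlen; ++k)
      x[k] = 2.0 * X(0, j) - X(padlen - k, j);
    for (int k = 0; k < n; ++k) x[padlen + k] = X(k, j);
    for (int k = 0; k < padlen; ++k)
      x[padlen + n + k] = 2.0 * X(n - 1, j) - X(n - 2 - k, j);

    for (int pass = 0; pass < 2; ++pass) {
      for (int t = 0; t < m; ++t) {
        double acc = 0.0;
        const int kb = std::min(nb - 1, t);
        for (int k = 0; k <= kb; ++k) acc += b[k] * x[t - k];
        const int ka = std::min(na - 1, t);
        for (int k = 1; k <= ka; ++k) acc -= a[k] * y[t - k];
        y[t] = acc;
      }
      // reverse for the second pass / final orientation
      std::reverse(y.begin(), y.end());
      x.swap(y);
    }
    for (int k = 0; k < n; ++k) out(k, j) = x[padlen + k];
  }
  return out;
}
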