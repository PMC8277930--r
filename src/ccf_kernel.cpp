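#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson correlations between two aligned segments at integer sample
// lags. A positive lag k correlates x[i] with y[i + k] (y shifted later),
// using only the n - |k| overlapping samples. Two-pass (mean-centered)
// sums so results agree with a naive R oracle to machine precision.
// Zero-variance overlaps yield NA.
// [[Rcpp::export]]
NumericVector ccf_lags_kernel(NumericVector x, NumericVector y,
                              IntegerVector lags) {
  const int n = x.size();
  const int L = lags.size();
  NumericVector out(L);
  if (y.size() != n) stop("x and y must have equal length");
  for (int j = 0; j < L; ++j) {
    const int k = lags[j];
    const int m = n - std::abs(k);
    if (m < 3) { out[j] = NA_REAL; continue; }
    const int xo = k >= 0 ? 0 : -k;   // x starts here
    const int yo = k >= 0 ? k : 0;    // y starts here
    double mx = 0.0, my = 0.0;
    for (int i = 0; i < m; ++i) { mx += x[xo + i]; my += y[yo + i]; }
    mx /= m; my /= m;
    double sxx = 0.0, syy = 0.0, sxy = 0.0;
    for (int i = 0; i < m; ++i) {
      const double dx = x[xo + i] - mx;
      const double dy = y[yo + i] - my;
      sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
    }
    if (sxx <= 0.0 || syy <= 0.0) { out[j] = NA_REAL; continue; }
    out[j] = sxy / std::sqrt(sxx * syy);
  }
  return out;
}
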