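#include <Rcpp.h>
using namespace Rcpp;

// Causal raster-scan recursion for the lag-shifted autoregressive field
//   y(i,j) = intercept + sum_{k,l} b_{k,l} y(i-k, j-l) + noise(i,j)
// over the 8 lags {(k,l) : k,l in 0..2, k+l > 0} in canonical
// lexicographic order. Out-of-range lagged sites take the value `mu`
// (the stationary process mean), so the top/left boundary is seeded at
// equilibrium rather than at zero. Noise is supplied by the caller so
// all randomness stays in R's RNG stream.
// [[Rcpp::export(name = ".arFieldRecurse")]]
NumericMatrix ar_field_recurse(NumericMatrix noise, NumericVector b,
                               double intercept, double mu) {
  if (b.size() != 8)
    stop("expected 8 autoregressive coefficients");
  const int H = noise.nrow(), W = noise.ncol();
  static const int K[8] = {0, 0, 1, 1, 1, 2, 2, 2};
  static const int L[8] = {1, 2, 0, 1, 2, 0, 1, 2};
  NumericMatrix y(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = intercept + noise(i, j);
      for (int s = 0; s < 8; ++s) {
        const int ii = i - K[s], jj = j - L[s];
        acc += b[s] * ((ii >= 0 && jj >= 0) ? y(ii, jj) : mu);
      }
      y(i, j) = acc;
    }
  }
  return y;
}
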