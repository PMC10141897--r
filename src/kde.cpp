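#include <Rcpp.h>
using namespace Rcpp;

// Exact Gaussian kernel density (unnormalised) evaluated at each grid point.
// Valley positions only depend on the density up to a constant factor, so
// the 1/(n*h*sqrt(2*pi)) normalisation is omitted.
// [[Rcpp::export]]
NumericVector kde_eval_cpp(NumericVector x, NumericVector grid, double bw) {
  const int n = x.size(), m = grid.size();
  NumericVector out(m);
  const double inv2 = 1.0 / (2.0 * bw * bw);
  for (int j = 0; j < m; ++j) {
    const double g = grid[j];
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - g;
      s += std::exp(-d * d * inv2);
    }
    out[j] = s;
  }
  return out;
}
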