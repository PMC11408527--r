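#include <Rcpp.h>
using namespace Rcpp;

// Row-wise FIR convolution with an odd-length kernel and reflected
// boundaries (reflection about the edge sample, edge not duplicated).
// x: units x bins, g: kernel (unit sum, length 2h+1).
// [[Rcpp::export(name = ".smooth_rows_reflect")]]
NumericMatrix smooth_rows_reflect(NumericMatrix x, NumericVector g) {
  const int m = x.nrow(), n = x.ncol(), K = g.size(), h = (K - 1) / 2;
  if (K % 2 == 0) stop("kernel length must be odd");
  if (n <= h) stop("too few bins for the smoothing kernel");
  NumericMatrix out(m, n);
  for (int j = 0; j < n; ++j) {
    double* oc = &out(0, j);
    for (int k = -h; k <= h; ++k) {
      int jj = j + k;
      if (jj < 0) jj = -jj;
      else if (jj >= n) jj = 2 * n - 2 - jj;
      const double w = g[k + h];
      const double* xc = &x(0, jj);
      for (int i = 0; i < m; ++i) oc[i] += w * xc[i];
    }
  }
  return out;
}
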