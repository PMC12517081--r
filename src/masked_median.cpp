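#include <Rcpp.h>
using namespace Rcpp;

// 3x3 median filter that honours a keep-mask: masked pixels are excluded from
// every neighbourhood and left untouched; windows shrink at the image border
// (no padding). Matches the shrinking-window edge policy documented for the
// phasor smoothing step.
// [[Rcpp::export]]
NumericMatrix masked_median_cpp(NumericMatrix x, LogicalMatrix keep,
                                int iterations) {
  int nr = x.nrow(), nc = x.ncol();
  if (keep.nrow() != nr || keep.ncol() != nc)
    stop("mask dimensions must match image dimensions");
  NumericMatrix cur = clone(x);
  std::vector<double> buf;
  buf.reserve(9);
  for (int it = 0; it < iterations; ++it) {
    NumericMatrix nxt = clone(cur);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!keep(i, j)) continue;
        buf.clear();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
            if (!keep(ii, jj)) continue;
            buf.push_back(cur(ii, jj));
          }
        }
        int n = (int)buf.size();
        if (n == 0) continue;
        std::sort(buf.begin(), buf.end());
        nxt(i, j) = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
      }
    }
    cur = nxt;
  }
  return cur;
}
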