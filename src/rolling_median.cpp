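#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered running median with shrinking windows at the edges.
// For an even number of in-window values the lower median is returned.
// Window of length k at position i covers indices
// [i - (k-1)/2, i + k/2] (0-based, integer division), clipped to the signal.
// [[Rcpp::export]]
NumericVector rolling_median_lower(NumericVector x, int k) {
  const int n = x.size();
  if (k < 1) stop("window length must be >= 1");
  NumericVector out(n);
  const int left = (k - 1) / 2, right = k / 2;
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - left);
    int hi = std::min(n - 1, i + right);
    int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    // lower median: (m-1)/2-th order statistic (0-based)
    int idx = (m - 1) / 2;
    std::nth_element(buf.begin(), buf.begin() + idx, buf.end());
    out[i] = buf[idx];
  }
  return out;
}
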