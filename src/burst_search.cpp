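#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window burst criterion for one photon stream: photon i is "hot"
// if it belongs to any window of m consecutive photons whose local rate
// m / (t[last] - t[first]) exceeds F times the local background rate.
// Background is piecewise constant: rate[k] applies on
// [breaks[k], breaks[k+1]).

// [[Rcpp::export]]
LogicalVector cpp_sliding_hot(NumericVector t, int m, double F,
                              NumericVector bg_breaks,
                              NumericVector bg_rates) {
  const int n = t.size();
  LogicalVector hot(n, false);
  if (n < m) return hot;
  int kb = 0;
  const int nb = bg_rates.size();
  for (int i = 0; i + m - 1 < n; ++i) {
    double span = t[i + m - 1] - t[i];
    double tm = 0.5 * (t[i] + t[i + m - 1]);
    while (kb + 1 < nb && bg_breaks[kb + 1] <= tm) ++kb;
    while (kb > 0 && bg_breaks[kb] > tm) --kb;
    double thr = F * bg_rates[kb];
    bool ok = (span <= 0) ? true : ((double)m / span > thr);
    if (ok)
      for (int j = i; j < i + m; ++j) hot[j] = true;
  }
  return hot;
}
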