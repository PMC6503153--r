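#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window median of one column for odd window k, Tukey end rule
// (shrinking symmetric odd windows near the edges).
static void sliding_median(const double* x, int n, int k, double* out,
                           std::vector<double>& win) {
  int h = k / 2;
  // interior: maintain a sorted window, replace one element per step
  if (n >= k) {
    win.assign(x, x + k);
    std::sort(win.begin(), win.end());
    out[h] = win[h];
    for (int i = h + 1; i < n - h; ++i) {
      double drop = x[i - h - 1], add = x[i + h];
      win.erase(std::lower_bound(win.begin(), win.end(), drop));
      win.insert(std::upper_bound(win.begin(), win.end(), add), add);
      out[i] = win[h];
    }
  }
  // edges: median of shrinking symmetric windows
  int hmax = std::min(h, (n - 1) / 2);
  for (int i = 0; i < n; ++i) {
    bool interior = (n >= k) && i >= h && i < n - h;
    if (interior) continue;
    int hh = std::min(std::min(i, n - 1 - i), hmax);
    win.assign(x + i - hh, x + i + hh + 1);
    std::nth_element(win.begin(), win.begin() + hh, win.end());
    out[i] = win[hh];
  }
}

// Median-filter bank: applies sliding medians of each odd window length in
// `ks` to every column of `x` and returns the pointwise median across the
// bank outputs.
// [[Rcpp::export]]
NumericMatrix median_filter_bank_cpp(NumericMatrix x, IntegerVector ks) {
  int n = x.nrow(), p = x.ncol(), m = ks.size();
  NumericMatrix out(n, p);
  std::vector<double> win;
  std::vector<double> bank((size_t)n * m);
  std::vector<double> tmp(m);
  for (int j = 0; j < p; ++j) {
    const double* col = &x(0, j);
    for (int q = 0; q < m; ++q)
      sliding_median(col, n, ks[q], &bank[(size_t)q * n], win);
    for (int i = 0; i < n; ++i) {
      for (int q = 0; q < m; ++q) tmp[q] = bank[(size_t)q * n + i];
      std::nth_element(tmp.begin(), tmp.begin() + m / 2, tmp.end());
      double hi = tmp[m / 2];
      if (m % 2 == 1) {
        out(i, j) = hi;
      } else {
        double lo = *std::max_element(tmp.begin(), tmp.begin() + m / 2);
        out(i, j) = (lo + hi) / 2.0;
      }
    }
  }
  return out;
}
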