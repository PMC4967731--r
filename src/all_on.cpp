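#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rolling "all-organelles-polarized" baseline: for each pixel and frame,
// the arithmetic mean of the brightest 20% of intensities inside the
// window [t - half_window, t + half_window], clamped at the stack ends.
// The number of values averaged is ceil(0.2 * window_length), never < 1.
//
// arr is an (nx, ny, n) array in R's column-major layout, so a pixel's
// time series has stride nx*ny. Per frame the window is re-selected with
// nth_element (O(window)); cheap enough for movie-scale stacks and free
// of the bookkeeping a sliding order-statistic structure would need at
// the clamped ends where both window length and the 20% count vary.
// [[Rcpp::export]]
NumericVector cpp_all_on(NumericVector arr, int nx, int ny, int n,
                         int half_window) {
  if (half_window < 1) stop("half_window must be >= 1 frame");
  const R_xlen_t npix = (R_xlen_t)nx * ny;
  NumericVector out(no_init(arr.size()));
  std::vector<double> series(n), scratch(n);
  const double *src = arr.begin();
  double *dst = out.begin();

  for (R_xlen_t p = 0; p < npix; ++p) {
    for (int t = 0; t < n; ++t) series[t] = src[p + npix * t];
    for (int t = 0; t < n; ++t) {
      int t0 = t - half_window;
      int t1 = t + half_window;
      if (t0 < 0) t0 = 0;
      if (t1 >= n) t1 = n - 1;
      const int len = t1 - t0 + 1;
      const int k = (len + 4) / 5;  // ceil(0.2 * len), always >= 1
      std::copy(series.begin() + t0, series.begin() + t0 + len,
                scratch.begin());
      std::nth_element(scratch.begin(), scratch.begin() + (k - 1),
                       scratch.begin() + len, std::greater<double>());
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += scratch[i];
      dst[p + npix * t] = s / k;
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, n);
  return out;
}
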