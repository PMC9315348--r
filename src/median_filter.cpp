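#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect indexing: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// Per-band 2-D spatial median with an odd square window and reflect
// padding. x is a rows x cols x bands array.
// [[Rcpp::export(name = ".median_filter3d")]]
NumericVector median_filter3d(NumericVector x, int rows, int cols, int bands,
                              int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be an odd integer >= 1");
  int h = window / 2;
  NumericVector out(x.size());
  std::vector<double> buf(window * window);
  const int plane = rows * cols;
  for (int b = 0; b < bands; ++b) {
    const double *src = &x[b * plane];
    double *dst = &out[b * plane];
    for (int c = 0; c < cols; ++c) {
      for (int r = 0; r < rows; ++r) {
        int k = 0;
        for (int dc = -h; dc <= h; ++dc) {
          int cc = reflect(c + dc, cols);
          for (int dr = -h; dr <= h; ++dr) {
            int rr = reflect(r + dr, rows);
            buf[k++] = src[cc * rows + rr];
          }
        }
        int mid = k / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + k);
        dst[c * rows + r] = buf[mid];
      }
    }
  }
  return out;
}
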