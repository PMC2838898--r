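#include <Rcpp.h>
using namespace Rcpp;

// Symmetric reflection (edge repeated): maps any integer offset into [0, n).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Sliding window median with symmetric border reflection; window must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int window) {
  int nr = x.nrow(), nc = x.ncol(), r = window / 2;
  NumericMatrix out(nr, nc);
  int k = window * window;
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -r; di <= r; ++di)
          buf[m++] = x(reflect_idx(i + di, nr), jj);
      }
      // window odd => k odd => middle element is the median
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// 8-connected component labelling of a logical matrix; 0 = background,
// components numbered from 1 in column-major discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        int ci = stack.back().first, cj = stack.back().second;
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (m(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = cur;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
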