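#include <Rcpp.h>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// reflect index into [0, n-1] (symmetric half-sample reflection)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int jj = reflect(j + dj, nc);
        for (int di = -h; di <= h; ++di) {
          int ii = reflect(i + di, nr);
          buf.push_back(img(ii, jj));
        }
      }
      size_t m = buf.size() / 2;  // window*window is odd
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(i, j) = buf[m];
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask; labels assigned in
// row-major scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}
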