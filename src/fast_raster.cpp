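#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of the 1-cells of a binary raster.
// connectivity 4 (edge neighbours) or 8 (edge + corner). NA counts as
// background. Labels are 1..k in scan order; 0 is background, NA preserved.
// [[Rcpp::export]]
IntegerMatrix label_patches_cpp(NumericMatrix x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      lab(i, j) = NumericMatrix::is_na(x(i, j)) ? NA_INTEGER : 0;

  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (NumericMatrix::is_na(x(i, j)) || x(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (NumericMatrix::is_na(x(qi, qj)) || x(qi, qj) == 0) continue;
          if (lab(qi, qj) != 0) continue;
          lab(qi, qj) = next;
          stack.push_back(qi + qj * nr);
        }
      }
    }
  }
  return lab;
}

// Focal sum over a discrete disk: out(i,j) = sum of x over cells whose
// centre lies within radius_cells of (i,j)'s centre (focal cell included).
// NA in x contributes 0 to sums; area outside the raster contributes 0.
// Uses per-row chord half-widths over row prefix sums: O(n * kernel rows).
// [[Rcpp::export]]
NumericMatrix focal_disk_sum_cpp(NumericMatrix x, double radius_cells) {
  const int nr = x.nrow(), nc = x.ncol();
  const int R = (int)std::floor(radius_cells + 1e-9);
  const double r2 = radius_cells * radius_cells + 1e-9;

  // chord half-width per row offset dy: max dx with dx^2 + dy^2 <= r^2
  std::vector<int> hw(2 * R + 1);
  for (int dy = -R; dy <= R; ++dy)
    hw[dy + R] = (int)std::floor(std::sqrt(r2 - (double)dy * dy));

  // prefix sums along each row: P(i, j) = sum of x(i, 0..j-1), NA as 0
  std::vector<double> P((size_t)nr * (nc + 1), 0.0);
  for (int i = 0; i < nr; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nc; ++j) {
      double v = x(i, j);
      if (!NumericMatrix::is_na(v)) acc += v;
      P[(size_t)i * (nc + 1) + j + 1] = acc;
    }
  }

  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int lo = std::max(-R, -i), hi = std::min(R, nr - 1 - i);
    for (int dy = lo; dy <= hi; ++dy) {
      const double *row = &P[(size_t)(i + dy) * (nc + 1)];
      const int w = hw[dy + R];
      for (int j = 0; j < nc; ++j) {
        int a = std::max(0, j - w), b = std::min(nc - 1, j + w);
        out(i, j) += row[b + 1] - row[a];
      }
    }
  }
  return out;
}
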