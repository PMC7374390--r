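#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fill zero-valued (missing) depth pixels with the value of the
// Euclidean-nearest valid pixel. Ties broken by row-major scan order
// (top-left origin), so results are deterministic.
// [[Rcpp::export(name = ".nnfill_cpp")]]
NumericMatrix nnfill_cpp(NumericMatrix depth) {
  const int H = depth.nrow(), W = depth.ncol();
  NumericMatrix out = clone(depth);
  bool any_valid = false;
  for (int j = 0; j < W && !any_valid; ++j)
    for (int i = 0; i < H; ++i)
      if (depth(i, j) != 0) { any_valid = true; break; }
  if (!any_valid) stop("depth raster has no valid (non-zero) pixels");

  const int rmax = std::max(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (depth(i, j) != 0) continue;
      double best_d2 = -1;
      long best_key = -1;
      double best_val = 0;
      for (int r = 1; r <= rmax; ++r) {
        // Chebyshev ring at radius r
        for (int di = -r; di <= r; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          const bool edge_row = (di == -r || di == r);
          for (int dj = -r; dj <= r; edge_row ? ++dj : dj += 2 * r) {
            const int jj = j + dj;
            if (jj < 0 || jj >= W) continue;
            const double v = depth(ii, jj);
            if (v == 0) continue;
            const double d2 = (double)di * di + (double)dj * dj;
            const long key = (long)ii * W + jj;
            if (best_d2 < 0 || d2 < best_d2 ||
                (d2 == best_d2 && key < best_key)) {
              best_d2 = d2;
              best_key = key;
              best_val = v;
            }
          }
        }
        // a pixel in ring r' has distance >= r'; stop once no farther ring
        // can beat the current best
        if (best_d2 >= 0 && (double)(r + 1) * (r + 1) > best_d2) break;
      }
      out(i, j) = best_val;
    }
  }
  return out;
}
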