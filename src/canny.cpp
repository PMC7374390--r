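#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Canny edge detector on a single channel in [0,1]. Thresholds are on the
// 8-bit gradient-magnitude scale (Sobel response of a 0-255 image).
// [[Rcpp::export(name = ".canny_cpp")]]
LogicalMatrix canny_cpp(NumericMatrix img, double sigma, double low,
                        double high) {
  const int H = img.nrow(), W = img.ncol();

  // separable Gaussian blur, replicate borders
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double ks = 0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    ks += k[t + r];
  }
  for (double &v : k) v /= ks;

  NumericMatrix tmp(H, W), sm(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(W - 1, std::max(0, j + t));
        a += k[t + r] * img(i, jj);
      }
      tmp(i, j) = a;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(H - 1, std::max(0, i + t));
        a += k[t + r] * tmp(ii, j);
      }
      sm(i, j) = a * 255.0;
    }

  // Sobel gradients
  NumericMatrix gx(H, W), gy(H, W), mag(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int iu = std::max(0, i - 1), id = std::min(H - 1, i + 1);
      const int jl = std::max(0, j - 1), jr = std::min(W - 1, j + 1);
      gx(i, j) = (sm(iu, jr) + 2 * sm(i, jr) + sm(id, jr)) -
                 (sm(iu, jl) + 2 * sm(i, jl) + sm(id, jl));
      gy(i, j) = (sm(id, jl) + 2 * sm(id, j) + sm(id, jr)) -
                 (sm(iu, jl) + 2 * sm(iu, j) + sm(iu, jr));
      mag(i, j) = std::sqrt(gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j));
    }

  // non-maximum suppression along quantized gradient direction
  IntegerMatrix cls(H, W); // 0 none, 1 weak, 2 strong
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double m = mag(i, j);
      if (m < low) continue;
      double ang = std::atan2(gy(i, j), gx(i, j));
      if (ang < 0) ang += M_PI;
      int di1, dj1;
      if (ang < M_PI / 8 || ang >= 7 * M_PI / 8)      { di1 = 0; dj1 = 1; }
      else if (ang < 3 * M_PI / 8)                    { di1 = 1; dj1 = 1; }
      else if (ang < 5 * M_PI / 8)                    { di1 = 1; dj1 = 0; }
      else                                            { di1 = 1; dj1 = -1; }
      double m1 = 0, m2 = 0;
      int i1 = i + di1, j1 = j + dj1, i2 = i - di1, j2 = j - dj1;
      if (i1 >= 0 && i1 < H && j1 >= 0 && j1 < W) m1 = mag(i1, j1);
      if (i2 >= 0 && i2 < H && j2 >= 0 && j2 < W) m2 = mag(i2, j2);
      if (m >= m1 && m >= m2) cls(i, j) = (m >= high) ? 2 : 1;
    }

  // hysteresis: keep weak edges 8-connected to a strong edge
  LogicalMatrix out(H, W);
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (cls(i, j) == 2 && !out(i, j)) {
        out(i, j) = true;
        stack.push_back(std::make_pair(i, j));
        while (!stack.empty()) {
          int ci = stack.back().first, cj = stack.back().second;
          stack.pop_back();
          for (int di = -1; di <= 1; ++di)
            for (int dj = -1; dj <= 1; ++dj) {
              int ni = ci + di, nj = cj + dj;
              if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
              if (cls(ni, nj) >= 1 && !out(ni, nj)) {
                out(ni, nj) = true;
                stack.push_back(std::make_pair(ni, nj));
              }
            }
        }
      }
  return out;
}
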