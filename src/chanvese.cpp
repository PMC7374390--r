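#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-phase Chan-Vese level-set evolution (semi-implicit Gauss-Seidel update).
// img: intensities in [0,1]; init: starting foreground; returns final phi,
// foreground = phi >= 0. Region means c1/c2 are recomputed every iteration.
// [[Rcpp::export(name = ".chanvese_cpp")]]
NumericMatrix chanvese_cpp(NumericMatrix img, LogicalMatrix init, int iters,
                           double mu, double dt, double lambda1,
                           double lambda2, double eps) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix phi(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) phi(i, j) = init(i, j) ? 1.0 : -1.0;

  const double eta = 1e-8;
  for (int it = 0; it < iters; ++it) {
    // region means under the current contour
    double s1 = 0, s2 = 0;
    long n1 = 0, n2 = 0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        if (phi(i, j) >= 0) { s1 += img(i, j); ++n1; }
        else                { s2 += img(i, j); ++n2; }
      }
    const double c1 = n1 ? s1 / n1 : 0.0;
    const double c2 = n2 ? s2 / n2 : 0.0;

    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const int iu = i > 0 ? i - 1 : 0, id = i < H - 1 ? i + 1 : H - 1;
        const int jl = j > 0 ? j - 1 : 0, jr = j < W - 1 ? j + 1 : W - 1;
        const double p = phi(i, j);

        const double A = mu / std::sqrt(eta +
          (phi(i, jr) - p) * (phi(i, jr) - p) +
          0.25 * (phi(id, j) - phi(iu, j)) * (phi(id, j) - phi(iu, j)));
        const double Al = mu / std::sqrt(eta +
          (p - phi(i, jl)) * (p - phi(i, jl)) +
          0.25 * (phi(id, jl) - phi(iu, jl)) * (phi(id, jl) - phi(iu, jl)));
        const double B = mu / std::sqrt(eta +
          0.25 * (phi(i, jr) - phi(i, jl)) * (phi(i, jr) - phi(i, jl)) +
          (phi(id, j) - p) * (phi(id, j) - p));
        const double Bu = mu / std::sqrt(eta +
          0.25 * (phi(iu, jr) - phi(iu, jl)) * (phi(iu, jr) - phi(iu, jl)) +
          (p - phi(iu, j)) * (p - phi(iu, j)));

        const double d = eps / (M_PI * (eps * eps + p * p));
        const double diff = img(i, j) - c1, diff2 = img(i, j) - c2;
        const double num = p + dt * d *
          (A * phi(i, jr) + Al * phi(i, jl) + B * phi(id, j) + Bu * phi(iu, j)
           - lambda1 * diff * diff + lambda2 * diff2 * diff2);
        const double den = 1.0 + dt * d * (A + Al + B + Bu);
        phi(i, j) = num / den;
      }
    }
  }
  return phi;
}
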