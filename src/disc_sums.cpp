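#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<int> chord_halfwidths(double r) {
  const int R = (int)std::floor(r);
  std::vector<int> halfw(R + 1);
  for (int d = 0; d <= R; ++d)
    halfw[d] = (int)std::floor(std::sqrt(r * r - (double)d * d));
  return halfw;
}

// Sums of `a` over the inclusive Euclidean disc of radius r centred at every
// pixel, truncated at the image border (out-of-image pixels contribute
// nothing). O(H*W*r) via per-row prefix sums; exact up to summation order,
// so it matches a per-pixel brute-force loop to rounding error.
// [[Rcpp::export]]
NumericMatrix disc_window_sums(NumericMatrix a, double r) {
  if (r <= 0) stop("radius must be positive");
  const int H = a.nrow(), W = a.ncol();

  // prefix[i*(W+1) + j + 1] = sum of a(i, 0..j)
  std::vector<double> prefix((size_t)H * (W + 1), 0.0);
  for (int i = 0; i < H; ++i) {
    double s = 0.0;
    double *p = &prefix[(size_t)i * (W + 1)];
    for (int j = 0; j < W; ++j) { s += a(i, j); p[j + 1] = s; }
  }

  std::vector<int> halfw = chord_halfwidths(r);
  const int R = (int)halfw.size() - 1;

  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    const int dlo = std::max(-R, -i), dhi = std::min(R, H - 1 - i);
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int d = dlo; d <= dhi; ++d) {
        const int w = halfw[d < 0 ? -d : d];
        const int j0 = j - w < 0 ? 0 : j - w;
        const int j1 = j + w >= W ? W - 1 : j + w;
        const double *p = &prefix[(size_t)(i + d) * (W + 1)];
        s += p[j1 + 1] - p[j0];
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Fused kernel for the localized means: disc-window sums of the four fields
// I*w_in, w_in, I*w_out, w_out plus the unweighted side counts, in a single
// pass over shared prefix sums. Identical arithmetic to disc_window_sums
// applied field by field, just cache-friendlier.
// [[Rcpp::export]]
List local_sums(NumericMatrix image, NumericMatrix w_in, NumericMatrix w_out,
                LogicalMatrix inside, double r) {
  if (r <= 0) stop("radius must be positive");
  const int H = image.nrow(), W = image.ncol();
  const int NF = 6;

  // interleaved per-row prefix sums of the six fields
  std::vector<double> prefix((size_t)H * (W + 1) * NF, 0.0);
  for (int i = 0; i < H; ++i) {
    double acc[NF] = {0, 0, 0, 0, 0, 0};
    double *p = &prefix[(size_t)i * (W + 1) * NF];
    for (int j = 0; j < W; ++j) {
      const double I = image(i, j), wi = w_in(i, j), wo = w_out(i, j);
      const double in = inside(i, j) ? 1.0 : 0.0;
      acc[0] += I * wi; acc[1] += wi; acc[2] += I * wo; acc[3] += wo;
      acc[4] += in; acc[5] += 1.0 - in;
      double *q = p + (size_t)(j + 1) * NF;
      for (int f = 0; f < NF; ++f) q[f] = acc[f];
    }
  }

  std::vector<int> halfw = chord_halfwidths(r);
  const int R = (int)halfw.size() - 1;

  NumericMatrix num_in(H, W), den_in(H, W), num_out(H, W), den_out(H, W);
  IntegerMatrix n_in(H, W), n_out(H, W);
  for (int i = 0; i < H; ++i) {
    const int dlo = std::max(-R, -i), dhi = std::min(R, H - 1 - i);
    for (int j = 0; j < W; ++j) {
      double s[NF] = {0, 0, 0, 0, 0, 0};
      for (int d = dlo; d <= dhi; ++d) {
        const int w = halfw[d < 0 ? -d : d];
        const int j0 = j - w < 0 ? 0 : j - w;
        const int j1 = j + w >= W ? W - 1 : j + w;
        const double *row = &prefix[(size_t)(i + d) * (W + 1) * NF];
        const double *hi = row + (size_t)(j1 + 1) * NF;
        const double *lo = row + (size_t)j0 * NF;
        for (int f = 0; f < NF; ++f) s[f] += hi[f] - lo[f];
      }
      num_in(i, j) = s[0]; den_in(i, j) = s[1];
      num_out(i, j) = s[2]; den_out(i, j) = s[3];
      n_in(i, j) = (int)std::lround(s[4]);
      n_out(i, j) = (int)std::lround(s[5]);
    }
  }
  return List::create(_["num_in"] = num_in, _["den_in"] = den_in,
                      _["num_out"] = num_out, _["den_out"] = den_out,
                      _["n_in"] = n_in, _["n_out"] = n_out);
}
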