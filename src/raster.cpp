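#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a union of balls: voxel centres (0-based index i -> (i + 0.5) *
// voxel) lying within radius r of any supplied point are set to 1. Used for
// tube rasterization (balls along densely resampled centrelines), soma blobs
// and speckles.
// [[Rcpp::export]]
IntegerVector paint_balls_cpp(IntegerVector dims, NumericVector voxel,
                              NumericMatrix pts, NumericVector radius,
                              IntegerVector mask) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector out = mask.size() ? clone(mask)
                                  : IntegerVector((R_xlen_t)n1 * n2 * n3);
  const double v1 = voxel[0], v2 = voxel[1], v3 = voxel[2];
  for (int p = 0; p < pts.nrow(); ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    const double r = radius[p % radius.size()];
    const double r2 = r * r;
    const int i0 = std::max(0, (int)std::ceil((px - r) / v1 - 0.5));
    const int i1 = std::min(n1 - 1, (int)std::floor((px + r) / v1 - 0.5));
    const int j0 = std::max(0, (int)std::ceil((py - r) / v2 - 0.5));
    const int j1 = std::min(n2 - 1, (int)std::floor((py + r) / v2 - 0.5));
    const int k0 = std::max(0, (int)std::ceil((pz - r) / v3 - 0.5));
    const int k1 = std::min(n3 - 1, (int)std::floor((pz + r) / v3 - 0.5));
    for (int k = k0; k <= k1; ++k) {
      const double dz = (k + 0.5) * v3 - pz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = (j + 0.5) * v2 - py;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = (i + 0.5) * v1 - px;
          if (dx * dx + dyz2 <= r2)
            out[(R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = 1;
        }
      }
    }
  }
  return out;
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable 3D convolution with mirror (reflect) padding; kernels are
// normalized by the caller. Used for Gaussian filtering.
// [[Rcpp::export]]
NumericVector conv_sep3d_cpp(NumericVector arr, IntegerVector dims,
                             NumericVector k1, NumericVector k2,
                             NumericVector k3) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector a = clone(arr), b(ntot);
  const NumericVector* kern[3] = {&k1, &k2, &k3};

  for (int axis = 0; axis < 3; ++axis) {
    const NumericVector& k = *kern[axis];
    const int half = (k.size() - 1) / 2;
    const int n = (axis == 0) ? n1 : (axis == 1 ? n2 : n3);
    if ((int)k.size() == 1 && k[0] == 1.0) continue;
    for (int z = 0; z < n3; ++z)
      for (int y = 0; y < n2; ++y)
        for (int x = 0; x < n1; ++x) {
          double s = 0.0;
          for (int t = -half; t <= half; ++t) {
            int xi = x, yi = y, zi = z;
            if (axis == 0) xi = mirror_idx(x + t, n);
            else if (axis == 1) yi = mirror_idx(y + t, n);
            else zi = mirror_idx(z + t, n);
            s += k[t + half] *
                 a[(R_xlen_t)xi + (R_xlen_t)n1 * (yi + (R_xlen_t)n2 * zi)];
          }
          b[(R_xlen_t)x + (R_xlen_t)n1 * (y + (R_xlen_t)n2 * z)] = s;
        }
    std::swap(a, b);
  }
  return a;
}
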