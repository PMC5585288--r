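#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1D squared distance transform along a sampled line with sample spacing s
// (lower-envelope-of-parabolas algorithm). f holds squared distances on
// input, d receives the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double sq;
    while (true) {
      sq = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) /
           (2.0 * s2 * (q - v[k]));
      if (k > 0 && sq <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    if (k == 0 && sq <= z[0]) {
      // degenerate: never happens with z[0] = -inf, kept for safety
      sq = z[0];
    }
    k++;
    v[k] = q;
    z[k] = sq;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) k++;
    const double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance transform.
// mask: 0/1 integer array (column-major), dims: 3 dims, voxel: spacing per axis.
// Returns squared distance (in physical units) from each foreground voxel to
// the nearest background voxel centre; 0 on background voxels. Voxels outside
// the array are treated as foreground (the transform measures distance to
// background *within* the volume; an all-foreground stack yields large values).
// [[Rcpp::export]]
NumericVector edt_squared_cpp(IntegerVector mask, IntegerVector dims,
                              NumericVector voxel) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n1, voxel[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2, voxel[1]);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)n1 * j;
      const R_xlen_t stride = (R_xlen_t)n1 * n2;
      for (int k = 0; k < n3; ++k) f[k] = out[base + stride * k];
      dt1d(f, d, v, z, n3, voxel[2]);
      for (int k = 0; k < n3; ++k) out[base + stride * k] = d[k];
    }
  return out;
}
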