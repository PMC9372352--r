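#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// sampled at positions j*step for j = 0..n-1.  f holds squared distances,
// d receives the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  static const double INF = std::numeric_limits<double>::infinity();
  // parabolas are anchored only at finite sites; rows with no finite entry
  // stay at infinity until a later pass reaches them
  std::vector<int> sites;
  sites.reserve(n);
  for (int q = 0; q < n; ++q)
    if (f[q] < INF) sites.push_back(q);
  if (sites.empty()) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(sites.size());
  std::vector<double> z(sites.size() + 1);
  int k = 0;
  v[0] = sites[0];
  z[0] = -INF;
  z[1] = INF;
  for (size_t si = 1; si < sites.size(); ++si) {
    int q = sites[si];
    double xq = q * step;
    while (true) {
      double xv = v[k] * step;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact Euclidean distance transform in mm for a 3D mask with anisotropic
// voxel spacing.  Returns, for every voxel, the distance to the nearest
// mask voxel (0 on the mask itself).
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x (fastest-varying)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + plane * z];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + plane * z] = d[z];
    }
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
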