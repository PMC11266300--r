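#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Point-in-mesh voxelization by vertical-ray parity counting.  For every
// (x, y) voxel column a ray is cast along +z; crossings with the closed
// surface are collected per column and voxel centers with an odd number of
// crossings below them are inside.  Ray x/y positions are jittered by a tiny
// deterministic offset so rays never pass exactly through triangle edges.

// [[Rcpp::export(name = ".voxelizeParity")]]
LogicalVector voxelizeParity(NumericMatrix V, IntegerMatrix F,
                             IntegerVector dims, NumericVector spacing,
                             NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // deterministic irrational-ish jitter, far below voxel scale
  const double jx = 0.5e-4 * sx * std::sqrt(2.0);
  const double jy = 0.5e-4 * sy * std::sqrt(3.0);
  const double ox = origin[0] + jx, oy = origin[1] + jy, oz = origin[2];

  std::vector<std::vector<double>> crossings((size_t)nx * ny);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    double bx = V(ib, 0), by = V(ib, 1), bz = V(ib, 2);
    double cx = V(ic, 0), cy = V(ic, 1), cz = V(ic, 2);
    double xmin = std::min({ax, bx, cx}), xmax = std::max({ax, bx, cx});
    double ymin = std::min({ay, by, cy}), ymax = std::max({ay, by, cy});
    int i0 = std::max(0, (int)std::ceil((xmin - ox) / sx));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - ox) / sx));
    int j0 = std::max(0, (int)std::ceil((ymin - oy) / sy));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - oy) / sy));
    double e1x = bx - ax, e1y = by - ay;
    double e2x = cx - ax, e2y = cy - ay;
    double det = e1x * e2y - e2x * e1y;
    if (std::abs(det) < 1e-300) continue;  // triangle vertical in z: no area in xy
    for (int j = j0; j <= j1; ++j) {
      double py = oy + j * sy - ay;
      for (int i = i0; i <= i1; ++i) {
        double px = ox + i * sx - ax;
        double u = (px * e2y - e2x * py) / det;
        double v = (e1x * py - px * e1y) / det;
        if (u <= 0 || v <= 0 || u + v >= 1) continue;  // strict interior
        double z = az + u * (bz - az) + v * (cz - az);
        crossings[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), FALSE);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &zs = crossings[(size_t)i + (size_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      size_t m = zs.size();
      for (int k = 0; k < nz; ++k) {
        double z = oz + k * sz;
        size_t below = std::lower_bound(zs.begin(), zs.end(), z) - zs.begin();
        if (below & 1) out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = TRUE;
        if (below == m && (m % 2 == 0)) break;  // above the surface entirely
      }
    }
  }
  return out;
}
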