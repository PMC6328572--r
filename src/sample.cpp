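#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Sample a 3D lattice at arbitrary physical (mm) points.
// mode 0 = trilinear, 1 = nearest. Out-of-bounds points get `fill` and are
// reported in the `oob` logical vector.
// [[Rcpp::export(name = ".sample_volume_cpp")]]
List sample_volume_cpp(NumericVector vol, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericMatrix pts, int mode, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const int np = pts.nrow();
  NumericVector out(np);
  LogicalVector oob(np, false);

  for (int i = 0; i < np; ++i) {
    const double ix = (pts(i, 0) - origin[0]) / spacing[0];
    const double iy = (pts(i, 1) - origin[1]) / spacing[1];
    const double iz = (pts(i, 2) - origin[2]) / spacing[2];
    if (mode == 1) {
      const int x = (int)std::lround(ix), y = (int)std::lround(iy),
                z = (int)std::lround(iz);
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) {
        out[i] = fill; oob[i] = true; continue;
      }
      out[i] = vol[x + (R_xlen_t)y * nx + (R_xlen_t)z * sxy];
    } else {
      if (ix < 0 || ix > nx - 1 || iy < 0 || iy > ny - 1 ||
          iz < 0 || iz > nz - 1) {
        out[i] = fill; oob[i] = true; continue;
      }
      int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy),
          z0 = (int)std::floor(iz);
      if (x0 == nx - 1) --x0;
      if (y0 == ny - 1) --y0;
      if (z0 == nz - 1) --z0;
      const double tx = ix - x0, ty = iy - y0, tz = iz - z0;
      double acc = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double w = (dx ? tx : 1.0 - tx) * (dy ? ty : 1.0 - ty) *
                             (dz ? tz : 1.0 - tz);
            acc += w * vol[(x0 + dx) + (R_xlen_t)(y0 + dy) * nx +
                           (R_xlen_t)(z0 + dz) * sxy];
          }
      out[i] = acc;
    }
  }
  return List::create(_["values"] = out, _["oob"] = oob);
}

// Stamp a densely sampled polyline into distance / arc-length fields:
// for every voxel within rmax of any polyline sample, record the distance to
// the nearest sample (mm) and that sample's arc length. Fields may be updated
// incrementally (pass existing dist/arc to merge, e.g. for a second tube).
// [[Rcpp::export(name = ".stamp_polyline_cpp")]]
List stamp_polyline_cpp(IntegerVector dim, NumericVector spacing,
                        NumericVector origin, NumericMatrix pts,
                        NumericVector arclen, double rmax,
                        Nullable<NumericVector> dist0,
                        Nullable<NumericVector> arc0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  NumericVector dist = dist0.isNotNull()
                           ? clone(NumericVector(dist0.get()))
                           : NumericVector(n, R_PosInf);
  NumericVector arc = arc0.isNotNull() ? clone(NumericVector(arc0.get()))
                                       : NumericVector(n, NA_REAL);
  const int np = pts.nrow();
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    const int x0 = std::max(0, (int)std::ceil((px - rmax - origin[0]) / spacing[0]));
    const int x1 = std::min(nx - 1, (int)std::floor((px + rmax - origin[0]) / spacing[0]));
    const int y0 = std::max(0, (int)std::ceil((py - rmax - origin[1]) / spacing[1]));
    const int y1 = std::min(ny - 1, (int)std::floor((py + rmax - origin[1]) / spacing[1]));
    const int z0 = std::max(0, (int)std::ceil((pz - rmax - origin[2]) / spacing[2]));
    const int z1 = std::min(nz - 1, (int)std::floor((pz + rmax - origin[2]) / spacing[2]));
    const double r2max = rmax * rmax;
    for (int z = z0; z <= z1; ++z) {
      const double dz = origin[2] + z * spacing[2] - pz;
      for (int y = y0; y <= y1; ++y) {
        const double dy = origin[1] + y * spacing[1] - py;
        const double dzy = dz * dz + dy * dy;
        if (dzy > r2max) continue;
        const R_xlen_t base = (R_xlen_t)y * nx + (R_xlen_t)z * sxy;
        for (int x = x0; x <= x1; ++x) {
          const double dx = origin[0] + x * spacing[0] - px;
          const double d2 = dzy + dx * dx;
          if (d2 > r2max) continue;
          const R_xlen_t li = base + x;
          const double d = std::sqrt(d2);
          if (d < dist[li]) {
            dist[li] = d;
            arc[li] = arclen[p];
          }
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["arclen"] = arc);
}
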