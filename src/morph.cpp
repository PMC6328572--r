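#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline void build_offsets(int conn, const int *dim,
                                 std::vector<int> &dx, std::vector<int> &dy,
                                 std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        if (x == 0 && y == 0 && z == 0) continue;
        const int manh = std::abs(x) + std::abs(y) + std::abs(z);
        if (conn == 6 && manh != 1) continue;
        if (conn == 18 && manh > 2) continue;
        dx.push_back(x); dy.push_back(y); dz.push_back(z);
      }
  (void)dim;
}

// Seeded region growing: BFS over voxels with value in [lo, hi], reachable
// from the seed linear indices (0-based) under 6/18/26 connectivity.
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dim,
                              IntegerVector seeds, double lo, double hi,
                              int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<int> dx, dy, dz;
  build_offsets(conn, INTEGER(dim), dx, dy, dz);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.size(); ++s) {
    const R_xlen_t idx = seeds[s];
    if (idx < 0 || idx >= n) stop("seed index out of bounds");
    if (!out[idx] && vol[idx] >= lo && vol[idx] <= hi) {
      out[idx] = true;
      q.push(idx);
    }
  }
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  while (!q.empty()) {
    const R_xlen_t idx = q.front(); q.pop();
    const int z = (int)(idx / sxy);
    const int y = (int)((idx - (R_xlen_t)z * sxy) / nx);
    const int x = (int)(idx - (R_xlen_t)z * sxy - (R_xlen_t)y * nx);
    for (size_t k = 0; k < dx.size(); ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t j = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sxy;
      if (!out[j] && vol[j] >= lo && vol[j] <= hi) {
        out[j] = true;
        q.push(j);
      }
    }
  }
  return out;
}

static int sgn(int v) { return v > 0 ? 1 : (v < 0 ? -1 : 0); }
static int igcd(int a, int b) { while (b) { int t = a % b; a = b; b = t; } return a; }

// does a monotone axis-step path from voxel a to a+v exist inside `domain`?
// (prevents long moves from tunnelling through thin barriers)
static bool monotone_reachable(const int *dom, int nx, int ny, int nz,
                               int ax, int ay, int az,
                               int vx, int vy, int vz) {
  if (vx == 0 && vy == 0 && vz == 0) return true;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int d = 0; d < 3; ++d) {
    int ex = 0, ey = 0, ez = 0;
    if (d == 0) { if (vx == 0) continue; ex = sgn(vx); }
    if (d == 1) { if (vy == 0) continue; ey = sgn(vy); }
    if (d == 2) { if (vz == 0) continue; ez = sgn(vz); }
    const int bx = ax + ex, by = ay + ey, bz = az + ez;
    if (bx < 0 || bx >= nx || by < 0 || by >= ny || bz < 0 || bz >= nz)
      continue;
    if (!dom[bx + (R_xlen_t)by * nx + (R_xlen_t)bz * sxy]) continue;
    if (monotone_reachable(dom, nx, ny, nz, bx, by, bz,
                           vx - ex, vy - ey, vz - ez))
      return true;
  }
  return false;
}

// Geodesic distance (Dijkstra) from a source mask, propagating only through
// `domain`, with physical (mm) edge lengths. neigh = 26 uses the unit
// 3x3x3 neighbourhood; neigh = 124 uses the 5x5x5 neighbourhood restricted
// to gcd-reduced offsets (chamfer error ~2% of Euclidean). When `support`
// is true, a move is only allowed if a monotone staircase of unit steps
// inside the domain connects its endpoints (barrier-tight semantics for
// restricted dilation). Optionally weighted by a per-voxel cost multiplier
// (edge cost = length * mean cost). Returns list(dist, pred).
// [[Rcpp::export(name = ".geodesic_dist_cpp")]]
List geodesic_dist_cpp(LogicalVector source, LogicalVector domain,
                       IntegerVector dim, NumericVector spacing,
                       Nullable<NumericVector> cost_, double max_dist,
                       int neigh, bool support) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  std::vector<int> dx, dy, dz;
  if (neigh == 124) {
    for (int z = -2; z <= 2; ++z)
      for (int y = -2; y <= 2; ++y)
        for (int x = -2; x <= 2; ++x) {
          if (x == 0 && y == 0 && z == 0) continue;
          const int g = igcd(igcd(std::abs(x), std::abs(y)), std::abs(z));
          if (g != 1) continue;
          dx.push_back(x); dy.push_back(y); dz.push_back(z);
        }
  } else {
    build_offsets(neigh, INTEGER(dim), dx, dy, dz);
  }
  std::vector<double> elen(dx.size());
  for (size_t k = 0; k < dx.size(); ++k) {
    const double ex = dx[k] * spacing[0], ey = dy[k] * spacing[1],
                 ez = dz[k] * spacing[2];
    elen[k] = std::sqrt(ex * ex + ey * ey + ez * ez);
  }
  const double *cost = nullptr;
  NumericVector costv;
  if (cost_.isNotNull()) { costv = cost_.get(); cost = REAL(costv); }
  std::vector<int> domv(n);
  for (R_xlen_t i = 0; i < n; ++i) domv[i] = domain[i] ? 1 : 0;

  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, -1);
  typedef std::pair<double, R_xlen_t> PQE;
  std::priority_queue<PQE, std::vector<PQE>, std::greater<PQE>> pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (source[i] && domain[i]) { dist[i] = 0.0; pq.push(PQE(0.0, i)); }

  while (!pq.empty()) {
    const PQE top = pq.top(); pq.pop();
    const double d = top.first;
    const R_xlen_t idx = top.second;
    if (d > dist[idx]) continue;
    if (max_dist > 0 && d > max_dist) continue;
    const int z = (int)(idx / sxy);
    const int y = (int)((idx - (R_xlen_t)z * sxy) / nx);
    const int x = (int)(idx - (R_xlen_t)z * sxy - (R_xlen_t)y * nx);
    for (size_t k = 0; k < dx.size(); ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t j = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * sxy;
      if (!domain[j]) continue;
      if (support &&
          (std::abs(dx[k]) + std::abs(dy[k]) + std::abs(dz[k]) > 1) &&
          !monotone_reachable(domv.data(), nx, ny, nz, x, y, z,
                              dx[k], dy[k], dz[k]))
        continue;
      double w = elen[k];
      if (cost) w *= 0.5 * (cost[idx] + cost[j]);
      const double nd = d + w;
      if (nd < dist[j]) {
        dist[j] = nd;
        pred[j] = (int)idx;
        pq.push(PQE(nd, j));
      }
    }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n, double h) {
  std::vector<int> v(n);
  std::vector<double> zbuf(n + 1);
  int k = 0;
  v[0] = 0; zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    if (f[v[0]] == std::numeric_limits<double>::infinity()) {
      // no finite parabola yet
      k = 0; v[0] = q;
      zbuf[0] = -std::numeric_limits<double>::infinity();
      zbuf[1] = std::numeric_limits<double>::infinity();
      continue;
    }
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = std::numeric_limits<double>::infinity();
  }
  if (f[v[0]] == std::numeric_limits<double>::infinity()) {
    for (int q = 0; q < n; ++q) d[q] = std::numeric_limits<double>::infinity();
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = h2 * (q - p) * (q - p) + f[p];
  }
}

// Anisotropic squared Euclidean distance transform: distance (mm^2) from each
// voxel to the nearest foreground (mask == TRUE) voxel center.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)y * nx + (R_xlen_t)z * sxy;
        for (int x = 0; x < nx; ++x) f[x] = g[base + x];
        edt_1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) g[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = x + (R_xlen_t)z * sxy;
        for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
        edt_1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = x + (R_xlen_t)y * nx;
        for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * sxy];
        edt_1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * sxy] = d[z];
      }
  }
  return g;
}
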