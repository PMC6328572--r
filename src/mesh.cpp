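#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra on a scalar lattice: each cell is split into six
// tetrahedra sharing the 0-7 main diagonal, which makes face diagonals agree
// between neighbouring cells (watertight surface). Vertices are deduplicated
// by the lattice edge they lie on. "Inside" is value <= level; triangles are
// oriented with normals pointing toward values > level.
// [[Rcpp::export(name = ".marching_tetrahedra_cpp")]]
List marching_tetrahedra_cpp(NumericVector phi, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::map<std::pair<long long, long long>, int> edge_vert;

  long long cid[8];
  double cval[8];
  double cpos[8][3];

  auto edge_vertex = [&](int a, int b) -> int {
    long long ia = cid[a], ib = cid[b];
    double pa = cval[a], pb = cval[b];
    const double *xa = cpos[a], *xb = cpos[b];
    if (ia > ib) { std::swap(ia, ib); std::swap(pa, pb); std::swap(xa, xb); }
    auto key = std::make_pair(ia, ib);
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (level - pa) / (pb - pa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    vx.push_back(xa[0] + t * (xb[0] - xa[0]));
    vy.push_back(xa[1] + t * (xb[1] - xa[1]));
    vz.push_back(xa[2] + t * (xb[2] - xa[2]));
    const int id = (int)vx.size() - 1;
    edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int v0, int v1, int v2, const double dir[3]) {
    // orient: normal toward increasing value
    const double ax = vx[v1] - vx[v0], ay = vy[v1] - vy[v0],
                 az = vz[v1] - vz[v0];
    const double bx = vx[v2] - vx[v0], by = vy[v2] - vy[v0],
                 bz = vz[v2] - vz[v0];
    const double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
                 nzv = ax * by - ay * bx;
    if (nxv * dir[0] + nyv * dir[1] + nzv * dir[2] < 0.0) std::swap(v1, v2);
    fa.push_back(v0 + 1); fb.push_back(v1 + 1); fc.push_back(v2 + 1);
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        for (int k = 0; k < 8; ++k) {
          const int cx = x + (k & 1), cy = y + ((k >> 1) & 1),
                    cz = z + ((k >> 2) & 1);
          const R_xlen_t li = cx + (R_xlen_t)cy * nx + (R_xlen_t)cz * sxy;
          cid[k] = (long long)li;
          cval[k] = phi[li];
          cpos[k][0] = origin[0] + cx * spacing[0];
          cpos[k][1] = origin[1] + cy * spacing[1];
          cpos[k][2] = origin[2] + cz * spacing[2];
        }
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int in[4], nin = 0;
          for (int k = 0; k < 4; ++k)
            in[k] = (cval[tv[k]] <= level) ? (++nin, 1) : 0;
          if (nin == 0 || nin == 4) continue;
          // direction from inside centroid to outside centroid
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
          int niC = 0, noC = 0;
          for (int k = 0; k < 4; ++k) {
            if (in[k]) {
              for (int d = 0; d < 3; ++d) ci[d] += cpos[tv[k]][d];
              ++niC;
            } else {
              for (int d = 0; d < 3; ++d) co[d] += cpos[tv[k]][d];
              ++noC;
            }
          }
          double dir[3];
          for (int d = 0; d < 3; ++d) dir[d] = co[d] / noC - ci[d] / niC;

          if (nin == 1 || nin == 3) {
            // one vertex isolated: single triangle
            int iso = -1;
            for (int k = 0; k < 4; ++k)
              if ((nin == 1 && in[k]) || (nin == 3 && !in[k])) iso = k;
            int vids[3], m = 0;
            for (int k = 0; k < 4; ++k)
              if (k != iso) vids[m++] = edge_vertex(tv[iso], tv[k]);
            emit(vids[0], vids[1], vids[2], dir);
          } else {
            // 2-2 split: quad = two triangles
            int ins[2], outs[2], mi = 0, mo = 0;
            for (int k = 0; k < 4; ++k)
              if (in[k]) ins[mi++] = k; else outs[mo++] = k;
            const int e00 = edge_vertex(tv[ins[0]], tv[outs[0]]);
            const int e01 = edge_vertex(tv[ins[0]], tv[outs[1]]);
            const int e10 = edge_vertex(tv[ins[1]], tv[outs[0]]);
            const int e11 = edge_vertex(tv[ins[1]], tv[outs[1]]);
            emit(e00, e01, e11, dir);
            emit(e00, e11, e10, dir);
          }
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  const int nf = (int)fa.size();
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = fa[i]; F(i, 1) = fb[i]; F(i, 2) = fc[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
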