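#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// from morph.cpp
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing);

// Signed distance (mm) to the mask boundary: negative inside, positive
// outside, zero crossing midway between adjacent in/out voxel centers.
// [[Rcpp::export(name = ".signed_distance_cpp")]]
NumericVector signed_distance_cpp(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing) {
  const R_xlen_t n = mask.size();
  LogicalVector inv(n);
  for (R_xlen_t i = 0; i < n; ++i) inv[i] = !mask[i];
  NumericVector dOut = edt_sq_cpp(mask, dim, spacing);   // dist to fg
  NumericVector dIn = edt_sq_cpp(inv, dim, spacing);     // dist to bg
  NumericVector phi(n);
  for (R_xlen_t i = 0; i < n; ++i)
    phi[i] = std::sqrt(dOut[i]) - std::sqrt(dIn[i]);
  return phi;
}

// Edge-based (geodesic) level-set evolution with inside-negative phi:
//   phi_t = -prop * f * |grad phi|_godunov
//           + curv * f * kappa |grad phi|_central
//           - V . grad phi  with V = -adv * grad f   (attraction to edges)
// phi is re-distanced from the current mask every reinit_every iterations
// (mask-preserving). Returns list(phi, iterations, rms, converged).
// [[Rcpp::export(name = ".evolve_levelset_cpp")]]
List evolve_levelset_cpp(NumericVector phi_in, NumericVector f,
                         NumericVector fx, NumericVector fy, NumericVector fz,
                         IntegerVector dim, NumericVector spacing,
                         double prop, double curv, double adv,
                         int max_iter, double rms_tol, int reinit_every,
                         double band_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double hmin = std::min(hx, std::min(hy, hz));

  NumericVector phi = clone(phi_in);
  std::vector<double> dphi(n, 0.0);

  // CFL bound from global speed bounds
  double fmax = 0.0, vxm = 0.0, vym = 0.0, vzm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (f[i] > fmax) fmax = f[i];
    if (std::fabs(fx[i]) > vxm) vxm = std::fabs(fx[i]);
    if (std::fabs(fy[i]) > vym) vym = std::fabs(fy[i]);
    if (std::fabs(fz[i]) > vzm) vzm = std::fabs(fz[i]);
  }
  double denom = std::fabs(prop) * fmax / hmin +
                 2.0 * curv * fmax * (1.0 / (hx * hx) + 1.0 / (hy * hy) +
                                      1.0 / (hz * hz)) +
                 std::fabs(adv) * (vxm / hx + vym / hy + vzm / hz);
  if (denom < 1e-12) denom = 1e-12;
  const double dt = 0.45 / denom;

  int iter = 0;
  double rms = R_PosInf;
  bool converged = false;
  std::vector<R_xlen_t> active;
  active.reserve(n / 8);

  for (iter = 0; iter < max_iter; ++iter) {
    // rebuild active narrow band
    active.clear();
    for (R_xlen_t i = 0; i < n; ++i)
      if (std::fabs(phi[i]) < band_mm) active.push_back(i);
    if (active.empty()) break;

    double sum2 = 0.0;
    for (size_t a = 0; a < active.size(); ++a) {
      const R_xlen_t idx = active[a];
      const int z = (int)(idx / sxy);
      const int y = (int)((idx - (R_xlen_t)z * sxy) / nx);
      const int x = (int)(idx - (R_xlen_t)z * sxy - (R_xlen_t)y * nx);
      const int xm = x > 0 ? x - 1 : 0, xp = x < nx - 1 ? x + 1 : nx - 1;
      const int ym = y > 0 ? y - 1 : 0, yp = y < ny - 1 ? y + 1 : ny - 1;
      const int zm = z > 0 ? z - 1 : 0, zp = z < nz - 1 ? z + 1 : nz - 1;
      const double c = phi[idx];
      const double pxm = phi[xm + (R_xlen_t)y * nx + (R_xlen_t)z * sxy];
      const double pxp = phi[xp + (R_xlen_t)y * nx + (R_xlen_t)z * sxy];
      const double pym = phi[x + (R_xlen_t)ym * nx + (R_xlen_t)z * sxy];
      const double pyp = phi[x + (R_xlen_t)yp * nx + (R_xlen_t)z * sxy];
      const double pzm = phi[x + (R_xlen_t)y * nx + (R_xlen_t)zm * sxy];
      const double pzp = phi[x + (R_xlen_t)y * nx + (R_xlen_t)zp * sxy];

      const double Dmx = (c - pxm) / hx, Dpx = (pxp - c) / hx;
      const double Dmy = (c - pym) / hy, Dpy = (pyp - c) / hy;
      const double Dmz = (c - pzm) / hz, Dpz = (pzp - c) / hz;

      double dp = 0.0;
      const double F = prop * f[idx];
      if (F != 0.0) {
        double g2;
        if (F > 0.0) {
          const double ax = std::max(Dmx, 0.0), bx = std::min(Dpx, 0.0);
          const double ay = std::max(Dmy, 0.0), by = std::min(Dpy, 0.0);
          const double az = std::max(Dmz, 0.0), bz = std::min(Dpz, 0.0);
          g2 = ax * ax + bx * bx + ay * ay + by * by + az * az + bz * bz;
        } else {
          const double ax = std::min(Dmx, 0.0), bx = std::max(Dpx, 0.0);
          const double ay = std::min(Dmy, 0.0), by = std::max(Dpy, 0.0);
          const double az = std::min(Dmz, 0.0), bz = std::max(Dpz, 0.0);
          g2 = ax * ax + bx * bx + ay * ay + by * by + az * az + bz * bz;
        }
        dp -= F * std::sqrt(g2);
      }

      if (curv > 0.0 && f[idx] > 0.0) {
        const double px = (pxp - pxm) / (2.0 * hx);
        const double py = (pyp - pym) / (2.0 * hy);
        const double pz = (pzp - pzm) / (2.0 * hz);
        const double g2 = px * px + py * py + pz * pz;
        if (g2 > 1e-12) {
          const double pxx = (pxp - 2.0 * c + pxm) / (hx * hx);
          const double pyy = (pyp - 2.0 * c + pym) / (hy * hy);
          const double pzz = (pzp - 2.0 * c + pzm) / (hz * hz);
          // mixed second derivatives
          auto P = [&](int xi, int yi, int zi) {
            return phi[xi + (R_xlen_t)yi * nx + (R_xlen_t)zi * sxy];
          };
          const double pxy = (P(xp, yp, z) - P(xp, ym, z) - P(xm, yp, z) +
                              P(xm, ym, z)) / (4.0 * hx * hy);
          const double pxz = (P(xp, y, zp) - P(xp, y, zm) - P(xm, y, zp) +
                              P(xm, y, zm)) / (4.0 * hx * hz);
          const double pyz = (P(x, yp, zp) - P(x, ym, zp) - P(x, yp, zm) +
                              P(x, ym, zm)) / (4.0 * hy * hz);
          const double K = (pxx * (py * py + pz * pz) +
                            pyy * (px * px + pz * pz) +
                            pzz * (px * px + py * py) -
                            2.0 * (px * py * pxy + px * pz * pxz +
                                   py * pz * pyz)) / g2;
          dp += curv * f[idx] * K;
        }
      }

      if (adv != 0.0) {
        const double Vx = -adv * fx[idx];
        const double Vy = -adv * fy[idx];
        const double Vz = -adv * fz[idx];
        double at = 0.0;
        at += Vx * (Vx > 0.0 ? Dmx : Dpx);
        at += Vy * (Vy > 0.0 ? Dmy : Dpy);
        at += Vz * (Vz > 0.0 ? Dmz : Dpz);
        dp -= at;
      }

      dphi[idx] = dt * dp;
      sum2 += dphi[idx] * dphi[idx];
    }

    for (size_t a = 0; a < active.size(); ++a)
      phi[active[a]] += dphi[active[a]];
    rms = std::sqrt(sum2 / active.size());
    if (rms < rms_tol) { converged = true; ++iter; break; }

    if (reinit_every > 0 && (iter + 1) % reinit_every == 0) {
      LogicalVector m(n);
      for (R_xlen_t i = 0; i < n; ++i) m[i] = phi[i] <= 0.0;
      NumericVector nd = signed_distance_cpp(m, dim, spacing);
      for (R_xlen_t i = 0; i < n; ++i) phi[i] = nd[i];
    }
  }

  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["rms"] = rms, _["converged"] = converged);
}
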