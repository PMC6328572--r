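#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable correlation of a 3D lattice with a centered 1D kernel along one
// axis, mirror ("reflect-101") boundary.  dim = (nx, ny, nz), column-major
// with x fastest; axis is 0, 1 or 2.
// [[Rcpp::export(name = ".sep_correlate")]]
NumericVector sep_correlate(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume size does not match dim");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  if (klen % 2 == 0) stop("kernel length must be odd");

  NumericVector out(n);
  const int nax = dim[axis];
  if (nax < 2) stop("axis too short for filtering");

  R_xlen_t stride;
  if (axis == 0) stride = 1;
  else if (axis == 1) stride = nx;
  else stride = (R_xlen_t)nx * ny;

  // iterate over all 1D lines along `axis`
  const int n1 = (axis == 0) ? ny : nx;
  const int n2 = (axis == 2) ? ny : nz;
  R_xlen_t s1, s2;
  if (axis == 0) { s1 = nx; s2 = (R_xlen_t)nx * ny; }
  else if (axis == 1) { s1 = 1; s2 = (R_xlen_t)nx * ny; }
  else { s1 = 1; s2 = nx; }

  std::vector<double> line(nax);
  const double *kp = REAL(kernel);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      const R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < nax; ++i) line[i] = vol[base + i * stride];
      for (int i = 0; i < nax; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int idx = i + k - r;
          // mirror about edge samples: -1 -> 1, nax -> nax-2
          while (idx < 0 || idx >= nax) {
            if (idx < 0) idx = -idx;
            if (idx >= nax) idx = 2 * (nax - 1) - idx;
          }
          acc += kp[k] * line[idx];
        }
        out[base + i * stride] = acc;
      }
    }
  }
  return out;
}

// Per-voxel eigenvalues of the symmetric Hessian (sorted by |lambda|) and
// the Frangi vesselness response.  Inputs are the six second-derivative
// lattices (already gamma-normalized).  c2 <= 0 requests the data-adaptive
// structureness constant (half the maximum Frobenius norm).
// Returns list(response, l1, l2, l3, c_used).
// [[Rcpp::export(name = ".frangi_combine")]]
List frangi_combine(NumericVector dxx, NumericVector dyy, NumericVector dzz,
                    NumericVector dxy, NumericVector dxz, NumericVector dyz,
                    double alpha, double beta, double c_in, bool bright,
                    bool want_eigs) {
  const R_xlen_t n = dxx.size();
  NumericVector l1(n), l2(n), l3(n);

  // closed-form symmetric 3x3 eigenvalues (trigonometric method)
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = dxx[i], b = dyy[i], c = dzz[i];
    const double d = dxy[i], e = dyz[i], f = dxz[i];
    const double p1 = d * d + f * f + e * e;
    double e1, e2, e3;
    if (p1 < 1e-300) {
      e1 = a; e2 = b; e3 = c;
    } else {
      const double q = (a + b + c) / 3.0;
      const double p2 = (a - q) * (a - q) + (b - q) * (b - q) +
                        (c - q) * (c - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p ; r = det(B) / 2
      const double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      const double b12 = d / p, b13 = f / p, b23 = e / p;
      double rdet = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      rdet /= 2.0;
      if (rdet < -1.0) rdet = -1.0;
      if (rdet > 1.0) rdet = 1.0;
      const double phi = std::acos(rdet) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    // sort by absolute value
    double v[3] = {e1, e2, e3};
    for (int s = 0; s < 2; ++s)
      for (int t = 0; t < 2 - s; ++t)
        if (std::fabs(v[t]) > std::fabs(v[t + 1])) std::swap(v[t], v[t + 1]);
    l1[i] = v[0]; l2[i] = v[1]; l3[i] = v[2];
  }

  double c2 = c_in;
  if (c2 <= 0.0) {
    double smax = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double s2 = l1[i] * l1[i] + l2[i] * l2[i] + l3[i] * l3[i];
      if (s2 > smax) smax = s2;
    }
    c2 = 0.5 * std::sqrt(smax);
    if (c2 <= 0.0) c2 = 1.0;
  }

  NumericVector resp(n);
  const double a2 = 2.0 * alpha * alpha;
  const double b2 = 2.0 * beta * beta;
  const double cc2 = 2.0 * c2 * c2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double L2 = l2[i], L3 = l3[i];
    // polarity gate: bright tube on dark needs l2, l3 strongly negative
    if (bright ? (L2 > 0.0 || L3 > 0.0) : (L2 < 0.0 || L3 < 0.0)) {
      resp[i] = 0.0;
      continue;
    }
    const double aL2 = std::fabs(L2), aL3 = std::fabs(L3);
    if (aL3 < 1e-12) { resp[i] = 0.0; continue; }
    const double Ra = aL2 / aL3;
    const double Rb = std::fabs(l1[i]) / std::sqrt(aL2 * aL3);
    const double S2 = l1[i] * l1[i] + L2 * L2 + L3 * L3;
    resp[i] = (1.0 - std::exp(-(Ra * Ra) / a2)) *
              std::exp(-(Rb * Rb) / b2) *
              (1.0 - std::exp(-S2 / cc2));
  }

  if (want_eigs)
    return List::create(_["response"] = resp, _["l1"] = l1, _["l2"] = l2,
                        _["l3"] = l3, _["c_used"] = c2);
  return List::create(_["response"] = resp, _["c_used"] = c2);
}
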