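// Geometry kernels: orthographic z-buffer rasterization of a triangle mesh
// onto a pixel grid, and signed point-to-surface distances between meshes.

#include <Rcpp.h>
using namespace Rcpp;

// Pixel (r, c) (0-based) has centre x = (c - (W-1)/2) * mpp,
// y = ((H-1)/2 - r) * mpp; view direction is -z, keep the highest surface.
// [[Rcpp::export]]
NumericMatrix cpp_raster_zbuffer(NumericMatrix V, IntegerMatrix F,
                                 int width, int height, double mpp) {
  NumericMatrix zbuf(height, width);
  std::fill(zbuf.begin(), zbuf.end(), R_NegInf);
  const double cx = (width - 1) / 2.0, cy = (height - 1) / 2.0;
  const double eps = 1e-9;

  for (int f = 0; f < F.nrow(); ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    // vertex positions in pixel coordinates (col, row)
    const double x1 = V(a, 0) / mpp + cx, y1 = cy - V(a, 1) / mpp;
    const double x2 = V(b, 0) / mpp + cx, y2 = cy - V(b, 1) / mpp;
    const double x3 = V(c, 0) / mpp + cx, y3 = cy - V(c, 1) / mpp;
    const double z1 = V(a, 2), z2 = V(b, 2), z3 = V(c, 2);

    const double den = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (std::fabs(den) < 1e-14) continue;  // degenerate in projection

    int c0 = (int)std::floor(std::min(std::min(x1, x2), x3) - eps);
    int c1 = (int)std::ceil(std::max(std::max(x1, x2), x3) + eps);
    int r0 = (int)std::floor(std::min(std::min(y1, y2), y3) - eps);
    int r1 = (int)std::ceil(std::max(std::max(y1, y2), y3) + eps);
    c0 = std::max(c0, 0); r0 = std::max(r0, 0);
    c1 = std::min(c1, width - 1); r1 = std::min(r1, height - 1);

    for (int r = r0; r <= r1; ++r) {
      for (int cc = c0; cc <= c1; ++cc) {
        const double px = cc, py = r;
        const double l1 = ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / den;
        const double l2 = ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / den;
        const double l3 = 1.0 - l1 - l2;
        if (l1 < -1e-9 || l2 < -1e-9 || l3 < -1e-9) continue;
        const double z = l1 * z1 + l2 * z2 + l3 * z3;
        if (z > zbuf(r, cc)) zbuf(r, cc) = z;
      }
    }
  }
  return zbuf;
}

static inline void tri_closest(const double* p, const double* a,
                               const double* b, const double* c,
                               double* out) {
  // Ericson, Real-Time Collision Detection, closest point on triangle.
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  const double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  const double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  const double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  const double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    const double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  const double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  const double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    const double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  const double den = 1.0 / (va + vb + vc);
  const double v = vb * den, w = vc * den;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Signed distance from each row of P to the surface (V, F); sign from the
// normal of the nearest face (positive on the side the winding normal faces).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_signed_dist(NumericMatrix P, NumericMatrix V,
                                         IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  for (int ip = 0; ip < np; ++ip) {
    const double p[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    double best = R_PosInf, bestcp[3] = {0, 0, 0};
    int bestf = -1;
    for (int f = 0; f < nf; ++f) {
      const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      const double a[3] = {vx[ia], vy[ia], vz[ia]};
      const double b[3] = {vx[ib], vy[ib], vz[ib]};
      const double c[3] = {vx[ic], vy[ic], vz[ic]};
      double cp[3];
      tri_closest(p, a, b, c, cp);
      const double dx = p[0] - cp[0], dy = p[1] - cp[1], dz = p[2] - cp[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bestcp[0] = cp[0]; bestcp[1] = cp[1]; bestcp[2] = cp[2];
        bestf = f;
      }
    }
    const double d = std::sqrt(best);
    double s = 1.0;
    if (bestf >= 0) {
      const int ia = F(bestf, 0) - 1, ib = F(bestf, 1) - 1, ic = F(bestf, 2) - 1;
      const double ux = vx[ib] - vx[ia], uy = vy[ib] - vy[ia], uz = vz[ib] - vz[ia];
      const double wx = vx[ic] - vx[ia], wy = vy[ic] - vy[ia], wz = vz[ic] - vz[ia];
      const double nx = uy * wz - uz * wy;
      const double ny = uz * wx - ux * wz;
      const double nz = ux * wy - uy * wx;
      const double dot = nx * (p[0] - bestcp[0]) + ny * (p[1] - bestcp[1]) +
                         nz * (p[2] - bestcp[2]);
      if (dot < 0) s = -1.0;
    }
    out[ip] = s * d;
  }
  return out;
}
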