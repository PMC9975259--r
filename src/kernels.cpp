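#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Largest eigenvalue of a symmetric 3x3 matrix (Cardano / trigonometric form).
static double eig_max3(double a11, double a12, double a13,
                       double a22, double a23, double a33) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    double m = a11;
    if (a22 > m) m = a22;
    if (a33 > m) m = a33;
    return m;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
              (a33 - q) * (a33 - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // B = (A - qI) / p, r = det(B) / 2
  double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double r = (b11 * (b22 * b33 - b23 * b23) -
              b12 * (b12 * b33 - b23 * b13) +
              b13 * (b12 * b23 - b22 * b13)) / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  return q + 2.0 * p * std::cos(phi);
}

// axial dispersion on [0,1] from an accumulated (unnormalized) dyadic tensor
static double dispersion_from_dyad(double t11, double t12, double t13,
                                   double t22, double t23, double t33,
                                   double wsum) {
  double l1 = eig_max3(t11 / wsum, t12 / wsum, t13 / wsum,
                       t22 / wsum, t23 / wsum, t33 / wsum);
  double rad = (3.0 * l1 - 1.0) / 2.0;
  if (rad < 0.0) rad = 0.0;
  double v = 1.0 - std::sqrt(rad);
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// Weighted vector summation on one 2D plane. Axial (doubled-angle)
// orientation per pixel from intensity-weighted offset vectors within a
// physical radius R. Angle in radians [0, pi), resultant length in [0,1].
// Only pixels with compute == TRUE are evaluated.
// [[Rcpp::export]]
List cpp_wvs2d(NumericMatrix img, double px, double py, double R,
               LogicalMatrix compute) {
  int nx = img.nrow(), ny = img.ncol();
  int mx = (int)std::floor(R / px), my = (int)std::floor(R / py);
  std::vector<int> dx, dy;
  std::vector<double> c2, s2;
  for (int a = -mx; a <= mx; ++a) {
    for (int b = -my; b <= my; ++b) {
      if (a == 0 && b == 0) continue;
      double vx = a * px, vy = b * py;
      if (vx * vx + vy * vy <= R * R) {
        double ang = std::atan2(vy, vx);
        dx.push_back(a);
        dy.push_back(b);
        c2.push_back(std::cos(2.0 * ang));
        s2.push_back(std::sin(2.0 * ang));
      }
    }
  }
  int noff = (int)dx.size();
  NumericMatrix angle(nx, ny), res(nx, ny);
  std::fill(angle.begin(), angle.end(), NA_REAL);
  std::fill(res.begin(), res.end(), NA_REAL);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!compute(i, j)) continue;
      double Sx = 0.0, Sy = 0.0, W = 0.0;
      for (int k = 0; k < noff; ++k) {
        int qi = i + dx[k], qj = j + dy[k];
        if (qi < 0 || qi >= nx || qj < 0 || qj >= ny) continue;
        double w = img(qi, qj);
        if (w <= 0.0) continue;
        Sx += w * c2[k];
        Sy += w * s2[k];
        W += w;
      }
      if (W > 0.0) {
        double a = 0.5 * std::atan2(Sy, Sx);
        if (a < 0.0) a += M_PI;
        if (a >= M_PI) a -= M_PI;
        angle(i, j) = a;
        res(i, j) = std::sqrt(Sx * Sx + Sy * Sy) / W;
      } else {
        angle(i, j) = NA_REAL;
        res(i, j) = 0.0;
      }
    }
  }
  return List::create(_["angle"] = angle, _["resultant"] = res);
}

static std::vector<int> sphere_offsets(const IntegerVector &dim,
                                       const NumericVector &pitch,
                                       double radius,
                                       std::vector<int> &ox,
                                       std::vector<int> &oy,
                                       std::vector<int> &oz) {
  double px = pitch[0], py = pitch[1], pz = pitch[2];
  // offsets beyond the array extent can never be in bounds
  int mx = std::min((int)std::floor(radius / px), dim[0] - 1);
  int my = std::min((int)std::floor(radius / py), dim[1] - 1);
  int mz = std::min((int)std::floor(radius / pz), dim[2] - 1);
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        double vx = a * px, vy = b * py, vz = c * pz;
        if (vx * vx + vy * vy + vz * vz <= radius * radius) {
          ox.push_back(a);
          oy.push_back(b);
          oz.push_back(c);
        }
      }
  return ox;
}

// Directional variance: confidence-weighted dyadic tensor of axial unit
// vectors over a spherical physical window, V = 1 - sqrt((3*lambda1 - 1)/2).
// [[Rcpp::export]]
NumericVector cpp_directional_variance(NumericVector ux, NumericVector uy,
                                       NumericVector uz, NumericVector w,
                                       LogicalVector mask, IntegerVector dim,
                                       NumericVector pitch, double radius,
                                       int min_count) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> ox, oy, oz;
  sphere_offsets(dim, pitch, radius, ox, oy, oz);
  int noff = (int)ox.size();
  NumericVector out(nx * ny * nz, NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        double t11 = 0, t12 = 0, t13 = 0, t22 = 0, t23 = 0, t33 = 0;
        double wsum = 0.0;
        int cnt = 0;
        for (int o = 0; o < noff; ++o) {
          int qi = i + ox[o], qj = j + oy[o], qk = k + oz[o];
          if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 || qk >= nz)
            continue;
          R_xlen_t q = (R_xlen_t)qi + nx * ((R_xlen_t)qj + (R_xlen_t)ny * qk);
          if (!mask[q]) continue;
          double wi = w[q];
          if (!(wi > 0.0)) continue;
          double a = ux[q], b = uy[q], c = uz[q];
          t11 += wi * a * a;
          t12 += wi * a * b;
          t13 += wi * a * c;
          t22 += wi * b * b;
          t23 += wi * b * c;
          t33 += wi * c * c;
          wsum += wi;
          ++cnt;
        }
        if (cnt < min_count || wsum <= 0.0) continue;
        out[idx] = dispersion_from_dyad(t11, t12, t13, t22, t23, t33, wsum);
      }
  out.attr("dim") = dim;
  return out;
}

// Local coverage: on-mask voxel fraction within the in-bounds part of a
// spherical (or cubic, Chebyshev-metric) physical window; defined on mask
// voxels only.
// [[Rcpp::export]]
NumericVector cpp_local_coverage(LogicalVector mask, IntegerVector dim,
                                 NumericVector pitch, double radius,
                                 bool cube) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> ox, oy, oz;
  if (cube) {
    int mx = std::min((int)std::floor(radius / pitch[0]), nx - 1);
    int my = std::min((int)std::floor(radius / pitch[1]), ny - 1);
    int mz = std::min((int)std::floor(radius / pitch[2]), nz - 1);
    for (int a = -mx; a <= mx; ++a)
      for (int b = -my; b <= my; ++b)
        for (int c = -mz; c <= mz; ++c) {
          ox.push_back(a); oy.push_back(b); oz.push_back(c);
        }
  } else
    sphere_offsets(dim, pitch, radius, ox, oy, oz);
  int noff = (int)ox.size();
  NumericVector out(nx * ny * nz, NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        int inb = 0, on = 0;
        for (int o = 0; o < noff; ++o) {
          int qi = i + ox[o], qj = j + oy[o], qk = k + oz[o];
          if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 || qk >= nz)
            continue;
          ++inb;
          R_xlen_t q = (R_xlen_t)qi + nx * ((R_xlen_t)qj + (R_xlen_t)ny * qk);
          if (mask[q]) ++on;
        }
        out[idx] = (double)on / (double)inb;
      }
  out.attr("dim") = dim;
  return out;
}

// Waviness: from each valid voxel trace bidirectionally along the local
// axial orientation (nearest-voxel lookup, fixed physical step, sign chosen
// to minimize turning) and take the axial dispersion of the sampled
// orientations along the path.
// [[Rcpp::export]]
NumericVector cpp_trace_waviness(NumericVector ux, NumericVector uy,
                                 NumericVector uz, LogicalVector valid,
                                 IntegerVector dim, NumericVector pitch,
                                 double trace_length, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double px = pitch[0], py = pitch[1], pz = pitch[2];
  int nstep = (int)std::floor((trace_length / 2.0) / step);
  NumericVector out(nx * ny * nz, NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!valid[idx]) continue;
        double u0x = ux[idx], u0y = uy[idx], u0z = uz[idx];
        double t11 = u0x * u0x, t12 = u0x * u0y, t13 = u0x * u0z;
        double t22 = u0y * u0y, t23 = u0y * u0z, t33 = u0z * u0z;
        int n = 1;
        for (int dir = 0; dir < 2; ++dir) {
          double sgn = (dir == 0) ? 1.0 : -1.0;
          double posx = i * px, posy = j * py, posz = k * pz;
          double dxv = sgn * u0x, dyv = sgn * u0y, dzv = sgn * u0z;
          for (int s = 0; s < nstep; ++s) {
            posx += step * dxv;
            posy += step * dyv;
            posz += step * dzv;
            int qi = (int)std::floor(posx / px + 0.5);
            int qj = (int)std::floor(posy / py + 0.5);
            int qk = (int)std::floor(posz / pz + 0.5);
            if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 ||
                qk >= nz)
              break;
            R_xlen_t q =
                (R_xlen_t)qi + nx * ((R_xlen_t)qj + (R_xlen_t)ny * qk);
            if (!valid[q]) break;
            double ax = ux[q], ay = uy[q], az = uz[q];
            if (ax * dxv + ay * dyv + az * dzv < 0.0) {
              ax = -ax;
              ay = -ay;
              az = -az;
            }
            t11 += ax * ax;
            t12 += ax * ay;
            t13 += ax * az;
            t22 += ay * ay;
            t23 += ay * az;
            t33 += az * az;
            ++n;
            dxv = ax;
            dyv = ay;
            dzv = az;
          }
        }
        if (n < 3) continue;
        out[idx] = dispersion_from_dyad(t11, t12, t13, t22, t23, t33,
                                        (double)n);
      }
  out.attr("dim") = dim;
  return out;
}

// Rasterize fiber centerline sample points into an intensity volume with a
// Gaussian radial profile, tracking per-voxel nearest-centerline distance,
// tangent and fiber id for the analytic ground truth.
// pts, tans: m x 3 (micrometres / unit vectors); fid: 1-based fiber id.
// [[Rcpp::export]]
List cpp_splat_fibers(IntegerVector dim, NumericVector pitch,
                      NumericMatrix pts, NumericMatrix tans,
                      IntegerVector fid, NumericVector peak,
                      NumericVector rho) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double px = pitch[0], py = pitch[1], pz = pitch[2];
  R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  NumericVector inten(nv, 0.0), dmin(nv, R_PosInf);
  NumericVector tx(nv, NA_REAL), ty(nv, NA_REAL), tz(nv, NA_REAL);
  IntegerVector id(nv, NA_INTEGER);
  int m = pts.nrow();
  for (int p = 0; p < m; ++p) {
    double cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    double sg = rho[p] / 2.0;
    double h = 3.0 * sg > rho[p] ? 3.0 * sg : rho[p];
    int i0 = (int)std::ceil((cx - h) / px), i1 = (int)std::floor((cx + h) / px);
    int j0 = (int)std::ceil((cy - h) / py), j1 = (int)std::floor((cy + h) / py);
    int k0 = (int)std::ceil((cz - h) / pz), k1 = (int)std::floor((cz + h) / pz);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    if (i1 >= nx) i1 = nx - 1;
    if (j1 >= ny) j1 = ny - 1;
    if (k1 >= nz) k1 = nz - 1;
    double inv2s2 = 1.0 / (2.0 * sg * sg);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double ddx = i * px - cx, ddy = j * py - cy, ddz = k * pz - cz;
          double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          double d = std::sqrt(d2);
          R_xlen_t q = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
          double val = peak[p] * std::exp(-d2 * inv2s2);
          if (val > inten[q]) inten[q] = val;
          if (d < dmin[q]) {
            dmin[q] = d;
            tx[q] = tans(p, 0);
            ty[q] = tans(p, 1);
            tz[q] = tans(p, 2);
            id[q] = fid[p];
          }
        }
  }
  inten.attr("dim") = dim;
  dmin.attr("dim") = dim;
  tx.attr("dim") = dim;
  ty.attr("dim") = dim;
  tz.attr("dim") = dim;
  id.attr("dim") = dim;
  return List::create(_["intensity"] = inten, _["dmin"] = dmin, _["tx"] = tx,
                      _["ty"] = ty, _["tz"] = tz, _["fiber_id"] = id);
}

// Three plane-projection angle fields from one 3D spherical window:
// each in-window voxel q contributes its intensity-weighted doubled-angle
// vector of the offset (q - p) projected on the xy, zx and yz planes.
// Offsets perpendicular to a plane carry no information for it and are
// skipped for that plane only. Angles in radians: theta in [0,pi) from
// +x toward +y, beta in [0,pi) from +x toward +z, alpha_yz in [0,pi)
// from +y toward +z (the caller converts alpha_yz to gamma).
// [[Rcpp::export]]
List cpp_wvs3d_planes(NumericVector img, LogicalVector mask,
                      IntegerVector dim, NumericVector pitch, double R) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double px = pitch[0], py = pitch[1], pz = pitch[2];
  int mx = (int)std::floor(R / px);
  int my = (int)std::floor(R / py);
  int mz = (int)std::floor(R / pz);
  std::vector<int> ox, oy, oz;
  std::vector<double> ct, st, cb, sb, cg, sg;
  std::vector<signed char> vt, vb, vg;
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        double vx = a * px, vy = b * py, vz = c * pz;
        if (vx * vx + vy * vy + vz * vz > R * R) continue;
        ox.push_back(a); oy.push_back(b); oz.push_back(c);
        bool t_ok = (vx != 0.0 || vy != 0.0);
        bool b_ok = (vx != 0.0 || vz != 0.0);
        bool g_ok = (vy != 0.0 || vz != 0.0);
        vt.push_back(t_ok); vb.push_back(b_ok); vg.push_back(g_ok);
        double at = t_ok ? std::atan2(vy, vx) : 0.0;
        double ab = b_ok ? std::atan2(vz, vx) : 0.0;
        double ag = g_ok ? std::atan2(vz, vy) : 0.0;
        ct.push_back(std::cos(2 * at)); st.push_back(std::sin(2 * at));
        cb.push_back(std::cos(2 * ab)); sb.push_back(std::sin(2 * ab));
        cg.push_back(std::cos(2 * ag)); sg.push_back(std::sin(2 * ag));
      }
  int noff = (int)ox.size();
  R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  NumericVector theta(nv, NA_REAL), beta(nv, NA_REAL), ayz(nv, NA_REAL);
  NumericVector rt(nv, NA_REAL), rb(nv, NA_REAL), rg(nv, NA_REAL);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        double Stx = 0, Sty = 0, Wt = 0;
        double Sbx = 0, Sby = 0, Wb = 0;
        double Sgx = 0, Sgy = 0, Wg = 0;
        for (int o = 0; o < noff; ++o) {
          int qi = i + ox[o], qj = j + oy[o], qk = k + oz[o];
          if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 ||
              qk >= nz)
            continue;
          R_xlen_t q = (R_xlen_t)qi + nx * ((R_xlen_t)qj + (R_xlen_t)ny * qk);
          double w = img[q];
          if (w <= 0.0) continue;
          if (vt[o]) { Stx += w * ct[o]; Sty += w * st[o]; Wt += w; }
          if (vb[o]) { Sbx += w * cb[o]; Sby += w * sb[o]; Wb += w; }
          if (vg[o]) { Sgx += w * cg[o]; Sgy += w * sg[o]; Wg += w; }
        }
        double a;
        if (Wt > 0) {
          a = 0.5 * std::atan2(Sty, Stx);
          if (a < 0) a += M_PI;
          if (a >= M_PI) a -= M_PI;
          theta[idx] = a; rt[idx] = std::sqrt(Stx * Stx + Sty * Sty) / Wt;
        } else rt[idx] = 0.0;
        if (Wb > 0) {
          a = 0.5 * std::atan2(Sby, Sbx);
          if (a < 0) a += M_PI;
          if (a >= M_PI) a -= M_PI;
          beta[idx] = a; rb[idx] = std::sqrt(Sbx * Sbx + Sby * Sby) / Wb;
        } else rb[idx] = 0.0;
        if (Wg > 0) {
          a = 0.5 * std::atan2(Sgy, Sgx);
          if (a < 0) a += M_PI;
          if (a >= M_PI) a -= M_PI;
          ayz[idx] = a; rg[idx] = std::sqrt(Sgx * Sgx + Sgy * Sgy) / Wg;
        } else rg[idx] = 0.0;
      }
  theta.attr("dim") = dim; beta.attr("dim") = dim; ayz.attr("dim") = dim;
  rt.attr("dim") = dim; rb.attr("dim") = dim; rg.attr("dim") = dim;
  return List::create(_["theta"] = theta, _["beta"] = beta,
                      _["alpha_yz"] = ayz, _["conf_theta"] = rt,
                      _["conf_beta"] = rb, _["conf_gamma"] = rg);
}

// Slice-wise 3x3 median filter (truncated window at image borders),
// the denoising step of the default masking rule.
// [[Rcpp::export]]
NumericVector cpp_median3x3(NumericVector vox, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double buf[9];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int n = 0;
        for (int b = j - 1; b <= j + 1; ++b) {
          if (b < 0 || b >= ny) continue;
          for (int a = i - 1; a <= i + 1; ++a) {
            if (a < 0 || a >= nx) continue;
            buf[n++] = vox[(R_xlen_t)a + nx * ((R_xlen_t)b + (R_xlen_t)ny * k)];
          }
        }
        std::sort(buf, buf + n);
        double med = (n % 2) ? buf[n / 2]
                             : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
        out[(R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = med;
      }
  out.attr("dim") = dim;
  return out;
}
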