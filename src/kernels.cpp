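// Compiled kernels for the registration core: trilinear sampling, the
// mask-restricted mean-square metric and its analytic gradient, and a
// separable anisotropic Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope algorithm) used for mm-exact margin expansion.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Grid {
  const double* v;
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;
};

Grid make_grid(const NumericVector& img, const IntegerVector& dim,
               const NumericVector& spc, const NumericVector& org) {
  Grid g;
  g.v = REAL(img);
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.sx = spc[0]; g.sy = spc[1]; g.sz = spc[2];
  g.ox = org[0]; g.oy = org[1]; g.oz = org[2];
  return g;
}

// Trilinear interpolation at a world point; false when outside the grid.
// Voxel centres define the grid: continuous index f = (w - origin)/spacing,
// in-bounds iff 0 <= f <= n-1 on every axis.
inline bool sample_tri(const Grid& g, double wx, double wy, double wz,
                       double& out) {
  const double fx = (wx - g.ox) / g.sx;
  const double fy = (wy - g.oy) / g.sy;
  const double fz = (wz - g.oz) / g.sz;
  if (!(fx >= 0.0 && fy >= 0.0 && fz >= 0.0 &&
        fx <= g.nx - 1.0 && fy <= g.ny - 1.0 && fz <= g.nz - 1.0))
    return false;
  int i = (int)fx; if (i > g.nx - 2) i = g.nx - 2;
  int j = (int)fy; if (j > g.ny - 2) j = g.ny - 2;
  int k = (int)fz; if (k > g.nz - 2) k = g.nz - 2;
  const double dx = fx - i, dy = fy - j, dz = fz - k;
  const size_t nx = (size_t)g.nx, nxy = (size_t)g.nx * g.ny;
  const double* v = g.v + (i + nx * j + nxy * k);
  const double c00 = v[0]       * (1 - dx) + v[1]           * dx;
  const double c10 = v[nx]      * (1 - dx) + v[nx + 1]      * dx;
  const double c01 = v[nxy]     * (1 - dx) + v[nxy + 1]     * dx;
  const double c11 = v[nxy + nx] * (1 - dx) + v[nxy + nx + 1] * dx;
  const double c0 = c00 * (1 - dy) + c10 * dy;
  const double c1 = c01 * (1 - dy) + c11 * dy;
  out = c0 * (1 - dz) + c1 * dz;
  return true;
}

} // namespace

// [[Rcpp::export]]
List cpp_trilinear(NumericVector img, IntegerVector dim, NumericVector spacing,
                   NumericVector origin, NumericMatrix pts) {
  Grid g = make_grid(img, dim, spacing, origin);
  const int n = pts.nrow();
  NumericVector out(n);
  LogicalVector inb(n);
  for (int r = 0; r < n; r++) {
    double val;
    if (sample_tri(g, pts(r, 0), pts(r, 1), pts(r, 2), val)) {
      out[r] = val; inb[r] = true;
    } else {
      out[r] = NA_REAL; inb[r] = false;
    }
  }
  return List::create(_["values"] = out, _["in_bounds"] = inb);
}

// Mean-square metric over mask voxels: mean over in-bounds mapped points of
// (moving(x) - fixed(T x))^2, with T x = R (x - c) + c + t.
// [[Rcpp::export]]
List cpp_masked_msq(NumericVector fixed, IntegerVector fdim,
                    NumericVector fspc, NumericVector forg,
                    NumericMatrix pts, NumericVector mvals,
                    NumericMatrix Rm, NumericVector center,
                    NumericVector trans) {
  Grid g = make_grid(fixed, fdim, fspc, forg);
  const int n = pts.nrow();
  const double r11 = Rm(0,0), r12 = Rm(0,1), r13 = Rm(0,2);
  const double r21 = Rm(1,0), r22 = Rm(1,1), r23 = Rm(1,2);
  const double r31 = Rm(2,0), r32 = Rm(2,1), r33 = Rm(2,2);
  const double cx = center[0], cy = center[1], cz = center[2];
  const double ax = cx + trans[0], ay = cy + trans[1], az = cz + trans[2];
  double acc = 0.0;
  int nin = 0;
  for (int r = 0; r < n; r++) {
    const double ux = pts(r, 0) - cx, uy = pts(r, 1) - cy, uz = pts(r, 2) - cz;
    const double yx = r11*ux + r12*uy + r13*uz + ax;
    const double yy = r21*ux + r22*uy + r23*uz + ay;
    const double yz = r31*ux + r32*uy + r33*uz + az;
    double f;
    if (sample_tri(g, yx, yy, yz, f)) {
      const double d = mvals[r] - f;
      acc += d * d;
      nin++;
    }
  }
  const double metric = (nin > 0) ? acc / nin : NA_REAL;
  return List::create(_["metric"] = metric, _["n_in"] = nin, _["n_total"] = n);
}

// Metric plus its gradient w.r.t. the six parameters (versor vector part
// v1,v2,v3 and translation t1,t2,t3). A1..A3 are dR/dv_k. The image gradient
// of the fixed volume is taken by central differences of the interpolant
// with world-space step h (mm). Voxels whose centre maps in bounds count in
// the metric; only voxels with all six offset samples in bounds contribute
// to the gradient.
// [[Rcpp::export]]
List cpp_masked_msq_grad(NumericVector fixed, IntegerVector fdim,
                         NumericVector fspc, NumericVector forg,
                         NumericMatrix pts, NumericVector mvals,
                         NumericMatrix Rm, NumericVector center,
                         NumericVector trans,
                         NumericMatrix A1, NumericMatrix A2, NumericMatrix A3,
                         double h) {
  Grid g = make_grid(fixed, fdim, fspc, forg);
  const int n = pts.nrow();
  const double r11 = Rm(0,0), r12 = Rm(0,1), r13 = Rm(0,2);
  const double r21 = Rm(1,0), r22 = Rm(1,1), r23 = Rm(1,2);
  const double r31 = Rm(2,0), r32 = Rm(2,1), r33 = Rm(2,2);
  const double cx = center[0], cy = center[1], cz = center[2];
  const double ax = cx + trans[0], ay = cy + trans[1], az = cz + trans[2];
  double acc = 0.0, gv1 = 0.0, gv2 = 0.0, gv3 = 0.0,
         gt1 = 0.0, gt2 = 0.0, gt3 = 0.0;
  int nin = 0;
  const double inv2h = 1.0 / (2.0 * h);
  for (int r = 0; r < n; r++) {
    const double ux = pts(r, 0) - cx, uy = pts(r, 1) - cy, uz = pts(r, 2) - cz;
    const double yx = r11*ux + r12*uy + r13*uz + ax;
    const double yy = r21*ux + r22*uy + r23*uz + ay;
    const double yz = r31*ux + r32*uy + r33*uz + az;
    double f0;
    if (!sample_tri(g, yx, yy, yz, f0)) continue;
    const double d = mvals[r] - f0;
    acc += d * d;
    nin++;
    double fxp, fxm, fyp, fym, fzp, fzm;
    if (sample_tri(g, yx + h, yy, yz, fxp) && sample_tri(g, yx - h, yy, yz, fxm) &&
        sample_tri(g, yx, yy + h, yz, fyp) && sample_tri(g, yx, yy - h, yz, fym) &&
        sample_tri(g, yx, yy, yz + h, fzp) && sample_tri(g, yx, yy, yz - h, fzm)) {
      const double gx = (fxp - fxm) * inv2h;
      const double gy = (fyp - fym) * inv2h;
      const double gz = (fzp - fzm) * inv2h;
      const double w = -2.0 * d;  // d/dtheta of d^2 = -2 d * dF/dtheta
      gt1 += w * gx; gt2 += w * gy; gt3 += w * gz;
      // dy/dv_k = A_k (x - c)
      const double b1x = A1(0,0)*ux + A1(0,1)*uy + A1(0,2)*uz;
      const double b1y = A1(1,0)*ux + A1(1,1)*uy + A1(1,2)*uz;
      const double b1z = A1(2,0)*ux + A1(2,1)*uy + A1(2,2)*uz;
      const double b2x = A2(0,0)*ux + A2(0,1)*uy + A2(0,2)*uz;
      const double b2y = A2(1,0)*ux + A2(1,1)*uy + A2(1,2)*uz;
      const double b2z = A2(2,0)*ux + A2(2,1)*uy + A2(2,2)*uz;
      const double b3x = A3(0,0)*ux + A3(0,1)*uy + A3(0,2)*uz;
      const double b3y = A3(1,0)*ux + A3(1,1)*uy + A3(1,2)*uz;
      const double b3z = A3(2,0)*ux + A3(2,1)*uy + A3(2,2)*uz;
      gv1 += w * (gx*b1x + gy*b1y + gz*b1z);
      gv2 += w * (gx*b2x + gy*b2y + gz*b2z);
      gv3 += w * (gx*b3x + gy*b3y + gz*b3z);
    }
  }
  NumericVector grad(6);
  double metric = NA_REAL;
  if (nin > 0) {
    metric = acc / nin;
    grad[0] = gv1 / nin; grad[1] = gv2 / nin; grad[2] = gv3 / nin;
    grad[3] = gt1 / nin; grad[4] = gt2 / nin; grad[5] = gt3 / nin;
  }
  return List::create(_["metric"] = metric, _["gradient"] = grad,
                      _["n_in"] = nin, _["n_total"] = n);
}

namespace {

// 1-D squared distance transform along a line with sample spacing s:
// d[q] = min_p f[p] + s^2 (q - p)^2 (lower envelope of parabolas).
void dt1d(const std::vector<double>& f, int n, double s,
          std::vector<double>& d, std::vector<int>& v,
          std::vector<double>& z) {
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    const double fq = f[q] + s2 * (double)q * q;
    for (;;) {
      const int p = v[k];
      const double sect = (fq - (f[p] + s2 * (double)p * p)) /
                          (2.0 * s2 * (q - p));
      if (sect <= z[k]) {
        k--;
      } else {
        k++;
        v[k] = q;
        z[k] = sect;
        z[k + 1] = std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    const int p = v[k];
    d[q] = f[p] + s2 * (double)(q - p) * (q - p);
  }
}

} // namespace

// Squared Euclidean distance (mm^2) to the nearest true voxel, with per-axis
// voxel spacing. Voxels with no true voxel anywhere stay at a large finite
// sentinel (>= 1e12).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  const double LARGE = 1e12;
  std::vector<double> D(n);
  for (size_t i = 0; i < n; i++) D[i] = mask[i] ? 0.0 : LARGE;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const size_t nxy = (size_t)nx * ny;
  // pass along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      const size_t base = (size_t)nx * j + nxy * k;
      for (int i = 0; i < nx; i++) f[i] = D[base + i];
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; i++) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      const size_t base = (size_t)i + nxy * k;
      for (int j = 0; j < ny; j++) f[j] = D[base + (size_t)nx * j];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; j++) D[base + (size_t)nx * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      const size_t base = (size_t)i + (size_t)nx * j;
      for (int k = 0; k < nz; k++) f[k] = D[base + nxy * k];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; k++) D[base + nxy * k] = d[k];
    }
  NumericVector out(n);
  std::copy(D.begin(), D.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
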