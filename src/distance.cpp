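#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Sentinel for "no feature in this line yet": large but finite so the
// parabola intersection arithmetic stays well defined. Squared distances in
// any realistic grid are < 1e8, so 1e15 never interferes.
static const double BIG = 1e15;

// 1-D squared-distance transform (lower envelope of parabolas), grid pitch s.
static void dt1d(const std::vector<double>& f, double s, int n,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double xs;
    while (true) {
      double xv = v[k] * s;
      xs = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (xs <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = xs;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest voxel
// center where mask is TRUE, with anisotropic spacing. Values >= 1e7 mean the
// mask is empty along every path (no feature anywhere).
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<double> g((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    g[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, sx, nx, d, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, sy, ny, d, v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nx * ny];
      dt1d(f, sz, nz, d, v, z);
      for (int k = 0; k < nz; ++k)
        g[base + (size_t)k * nx * ny] = std::sqrt(d[k]);
    }

  NumericVector out((R_xlen_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = g[i];
  return out;
}

// Exact distance (mm) from arbitrary world points to the nearest TRUE voxel
// center. `dmap` is the edt3d() result for the same mask, used only to bound
// the local exhaustive search; the returned distances are exact.
// [[Rcpp::export(name = ".nearest_mask_distance")]]
NumericVector nearest_mask_distance(NumericMatrix pts, LogicalVector mask,
                                    IntegerVector dims, NumericVector spacing,
                                    NumericVector origin, NumericVector dmap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const int n = pts.nrow();
  NumericVector out(n);

  for (int p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double cx = (px - origin[0]) / sx;  // continuous 0-based index
    double cy = (py - origin[1]) / sy;
    double cz = (pz - origin[2]) / sz;
    int ix = (int)std::lround(cx), iy = (int)std::lround(cy),
        iz = (int)std::lround(cz);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);
    size_t lin = (size_t)iz * nx * ny + (size_t)iy * nx + ix;
    double base = dmap[lin];
    if (base >= 1e7) { out[p] = R_PosInf; continue; }
    double ddx = px - (origin[0] + ix * sx);
    double ddy = py - (origin[1] + iy * sy);
    double ddz = pz - (origin[2] + iz * sz);
    double slack = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    double r = base + slack + 1e-9;  // upper bound on the true distance
    int kx = (int)std::ceil(r / sx) + 1;
    int ky = (int)std::ceil(r / sy) + 1;
    int kz = (int)std::ceil(r / sz) + 1;
    int x0 = std::max(ix - kx, 0), x1 = std::min(ix + kx, nx - 1);
    int y0 = std::max(iy - ky, 0), y1 = std::min(iy + ky, ny - 1);
    int z0 = std::max(iz - kz, 0), z1 = std::min(iz + kz, nz - 1);
    double best = R_PosInf;
    for (int k = z0; k <= z1; ++k) {
      double wz = origin[2] + k * sz - pz;
      double wz2 = wz * wz;
      if (wz2 > best) continue;
      for (int j = y0; j <= y1; ++j) {
        double wy = origin[1] + j * sy - py;
        double wyz = wz2 + wy * wy;
        if (wyz > best) continue;
        size_t row = (size_t)k * nx * ny + (size_t)j * nx;
        for (int i = x0; i <= x1; ++i) {
          if (!mask[row + i]) continue;
          double wx = origin[0] + i * sx - px;
          double d2 = wyz + wx * wx;
          if (d2 < best) best = d2;
        }
      }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// March from each start point along `dir` in steps of `step` (mm) until the
// first sample that is not bone (label outside 1..7) or falls outside the
// grid; returns the leading-run exit distance per start (0 if the start
// itself is not in bone). Boundary is reported at half a step past the last
// in-bone sample, matching the nearest-voxel ownership convention.
// [[Rcpp::export(name = ".march_exit")]]
NumericVector march_exit(NumericMatrix starts, NumericVector dir, double step,
                         double maxdist, IntegerVector lab, IntegerVector dims,
                         NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = starts.nrow();
  const int nsteps = (int)std::floor(maxdist / step);
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double px = starts(p, 0), py = starts(p, 1), pz = starts(p, 2);
    int runs = -1;
    for (int s = 0; s <= nsteps; ++s) {
      double x = px + s * step * dir[0];
      double y = py + s * step * dir[1];
      double z = pz + s * step * dir[2];
      int i = (int)std::lround((x - origin[0]) / spacing[0]);
      int j = (int)std::lround((y - origin[1]) / spacing[1]);
      int k = (int)std::lround((z - origin[2]) / spacing[2]);
      bool inb = false;
      if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz) {
        int v = lab[(size_t)k * nx * ny + (size_t)j * nx + i];
        inb = (v >= 1 && v <= 7);
      }
      if (!inb) { runs = s; break; }
    }
    if (runs == 0) out[p] = 0.0;
    else if (runs < 0) out[p] = maxdist;
    else out[p] = (runs - 1) * step + step / 2.0;
  }
  return out;
}
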