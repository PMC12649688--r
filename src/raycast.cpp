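#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Slab intersection of a ray with the voxel-grid bounding box.
// Returns false when the ray misses the box.
static bool box_clip(const double org[3], const double dir[3],
                     const double lo[3], const double hi[3],
                     double &t0, double &t1) {
  t0 = 0.0;
  t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (org[a] < lo[a] || org[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - org[a]) / dir[a];
      double tb = (hi[a] - org[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return true;
}

// Trilinear interpolation at a continuous grid coordinate g (voxel-center
// units), clamped to the grid so rays grazing the border stay defined.
static double trilerp(const NumericVector &vol, const int n[3],
                      double gx, double gy, double gz) {
  if (gx < 0) gx = 0; if (gx > n[0] - 1) gx = n[0] - 1;
  if (gy < 0) gy = 0; if (gy > n[1] - 1) gy = n[1] - 1;
  if (gz < 0) gz = 0; if (gz > n[2] - 1) gz = n[2] - 1;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
  if (ix > n[0] - 2) ix = n[0] - 2; if (ix < 0) ix = 0;
  if (iy > n[1] - 2) iy = n[1] - 2; if (iy < 0) iy = 0;
  if (iz > n[2] - 2) iz = n[2] - 2; if (iz < 0) iz = 0;
  double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  const int sx = 1, sy = n[0], sz = n[0] * n[1];
  const double *v = REAL(vol);
  int base = ix * sx + iy * sy + iz * sz;
  double c00 = v[base] * (1 - fx) + v[base + sx] * fx;
  double c10 = v[base + sy] * (1 - fx) + v[base + sy + sx] * fx;
  double c01 = v[base + sz] * (1 - fx) + v[base + sz + sx] * fx;
  double c11 = v[base + sz + sy] * (1 - fx) + v[base + sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Line integrals of an attenuation volume along source->detector-point rays.
// mu: column-major (nx, ny, nz) attenuation values (1/mm); det_pts: 3 x npix
// detector-point positions (mm); step: sampling step along the ray (mm).
// [[Rcpp::export(name = ".drr_integrate")]]
NumericVector drr_integrate(NumericVector mu, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericVector source, NumericMatrix det_pts,
                            double step) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (n[a] - 0.5) * spacing[a];
  }
  const int npix = det_pts.ncol();
  NumericVector out(npix);
  const double org[3] = {source[0], source[1], source[2]};
  for (int p = 0; p < npix; ++p) {
    double dir[3];
    double len = 0.0;
    for (int a = 0; a < 3; ++a) {
      dir[a] = det_pts(a, p) - org[a];
      len += dir[a] * dir[a];
    }
    len = std::sqrt(len);
    for (int a = 0; a < 3; ++a) dir[a] /= len;
    double t0, t1;
    if (!box_clip(org, dir, lo, hi, t0, t1) || t1 <= t0) { out[p] = 0.0; continue; }
    int nstep = (int)std::ceil((t1 - t0) / step);
    if (nstep < 1) nstep = 1;
    double ds = (t1 - t0) / nstep;
    double acc = 0.0;
    for (int k = 0; k < nstep; ++k) {
      double t = t0 + (k + 0.5) * ds;
      double gx = (org[0] + t * dir[0] - origin[0]) / spacing[0];
      double gy = (org[1] + t * dir[1] - origin[1]) / spacing[1];
      double gz = (org[2] + t * dir[2] - origin[2]) / spacing[2];
      acc += trilerp(mu, n, gx, gy, gz);
    }
    out[p] = acc * ds;
  }
  return out;
}

// Number of distinct mask voxels each ray passes through, by exact
// Amanatides-Woo voxel traversal (the limit of arbitrarily fine ray
// sampling). mask: column-major 0/1 integers.
// [[Rcpp::export(name = ".ray_voxel_counts")]]
IntegerVector ray_voxel_counts(IntegerVector mask, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericVector source, NumericMatrix det_pts) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (n[a] - 0.5) * spacing[a];
  }
  const int npix = det_pts.ncol();
  IntegerVector out(npix);
  const int *m = INTEGER(mask);
  const int sy = n[0], sz = n[0] * n[1];
  const double org[3] = {source[0], source[1], source[2]};
  const double inf = std::numeric_limits<double>::infinity();
  for (int p = 0; p < npix; ++p) {
    double dir[3];
    double len = 0.0;
    for (int a = 0; a < 3; ++a) {
      dir[a] = det_pts(a, p) - org[a];
      len += dir[a] * dir[a];
    }
    len = std::sqrt(len);
    for (int a = 0; a < 3; ++a) dir[a] /= len;
    double t0, t1;
    if (!box_clip(org, dir, lo, hi, t0, t1) || t1 <= t0) { out[p] = 0; continue; }
    // nudge inside the box to get a well-defined start voxel
    double eps = 1e-9 * (t1 - t0 + 1.0);
    double t = t0 + eps;
    int idx[3], stepv[3];
    double tmax[3], tdelta[3];
    for (int a = 0; a < 3; ++a) {
      double pos = org[a] + t * dir[a];
      int i = (int)std::floor((pos - lo[a]) / spacing[a]);
      if (i < 0) i = 0;
      if (i > n[a] - 1) i = n[a] - 1;
      idx[a] = i;
      if (dir[a] > 1e-12) {
        stepv[a] = 1;
        tmax[a] = (lo[a] + (i + 1) * spacing[a] - org[a]) / dir[a];
        tdelta[a] = spacing[a] / dir[a];
      } else if (dir[a] < -1e-12) {
        stepv[a] = -1;
        tmax[a] = (lo[a] + i * spacing[a] - org[a]) / dir[a];
        tdelta[a] = -spacing[a] / dir[a];
      } else {
        stepv[a] = 0;
        tmax[a] = inf;
        tdelta[a] = inf;
      }
    }
    int count = 0;
    while (true) {
      if (m[idx[0] + idx[1] * sy + idx[2] * sz]) ++count;
      int a = 0;
      if (tmax[1] < tmax[a]) a = 1;
      if (tmax[2] < tmax[a]) a = 2;
      if (tmax[a] > t1) break;
      idx[a] += stepv[a];
      if (idx[a] < 0 || idx[a] >= n[a]) break;
      tmax[a] += tdelta[a];
    }
    out[p] = count;
  }
  return out;
}
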