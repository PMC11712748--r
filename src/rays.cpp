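#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Exact voxel traversal (incremental Siddon-style grid stepping).
// Grid convention: org[] is the world position of the CENTER of voxel (0,0,0);
// voxel (i,j,k) spans [B + i*sp, B + (i+1)*sp) with B = org - sp/2.
// The ray starts at src and runs along unit direction dir for t in [0, inf);
// segments are returned in traversal order with t measured in mm from src.

struct Seg {
  int idx;
  double t0, t1;
};

static std::vector<Seg> traverse_grid(const int* dims, const double* sp,
                                      const double* org, const double* src,
                                      const double* dir) {
  std::vector<Seg> out;
  double B[3], E[3];
  for (int a = 0; a < 3; ++a) {
    B[a] = org[a] - 0.5 * sp[a];
    E[a] = B[a] + dims[a] * sp[a];
  }
  double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (src[a] <= B[a] || src[a] >= E[a]) return out;
    } else {
      double ta = (B[a] - src[a]) / dir[a];
      double tb = (E[a] - src[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (!(t1 > t0)) return out;
  const double eps = 1e-9 * (t1 - t0) + 1e-12;
  int iv[3], step[3];
  double tnext[3], dt[3];
  for (int a = 0; a < 3; ++a) {
    double p = src[a] + (t0 + eps) * dir[a];
    iv[a] = (int)std::floor((p - B[a]) / sp[a]);
    if (iv[a] < 0) iv[a] = 0;
    if (iv[a] >= dims[a]) iv[a] = dims[a] - 1;
    if (dir[a] > 1e-12) {
      step[a] = 1;
      dt[a] = sp[a] / dir[a];
      tnext[a] = ((B[a] + (iv[a] + 1) * sp[a]) - src[a]) / dir[a];
    } else if (dir[a] < -1e-12) {
      step[a] = -1;
      dt[a] = -sp[a] / dir[a];
      tnext[a] = ((B[a] + iv[a] * sp[a]) - src[a]) / dir[a];
    } else {
      step[a] = 0;
      dt[a] = std::numeric_limits<double>::infinity();
      tnext[a] = std::numeric_limits<double>::infinity();
    }
  }
  double t = t0;
  while (t < t1 - 1e-9) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double te = tnext[a] < t1 ? tnext[a] : t1;
    if (te > t) {
      Seg s;
      s.idx = iv[0] + dims[0] * (iv[1] + dims[1] * iv[2]);
      s.t0 = t;
      s.t1 = te;
      out.push_back(s);
    }
    t = te;
    if (tnext[a] >= t1) break;
    iv[a] += step[a];
    if (iv[a] < 0 || iv[a] >= dims[a]) break;
    tnext[a] += dt[a];
  }
  return out;
}

// [[Rcpp::export(name = ".trace_ray_cpp")]]
DataFrame trace_ray_cpp(IntegerVector dims, NumericVector spacing,
                        NumericVector origin, NumericVector source,
                        NumericVector target) {
  double dir[3], src[3];
  double nrm = 0.0;
  for (int a = 0; a < 3; ++a) {
    src[a] = source[a];
    dir[a] = target[a] - source[a];
    nrm += dir[a] * dir[a];
  }
  nrm = std::sqrt(nrm);
  if (nrm <= 0) stop("source and target coincide");
  for (int a = 0; a < 3; ++a) dir[a] /= nrm;
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  std::vector<Seg> segs = traverse_grid(d, sp, org, src, dir);
  int n = (int)segs.size();
  IntegerVector idx(n);
  NumericVector len(n), ts(n), te(n);
  for (int i = 0; i < n; ++i) {
    idx[i] = segs[i].idx + 1;  // 1-based linear index
    len[i] = segs[i].t1 - segs[i].t0;
    ts[i] = segs[i].t0;
    te[i] = segs[i].t1;
  }
  return DataFrame::create(_["voxel"] = idx, _["length_mm"] = len,
                           _["t_start_mm"] = ts, _["t_end_mm"] = te);
}

// Line integrals of density on the fluence grid.
// mode 0 (intra):     sum over in-mask voxels of density * segment length.
// mode 1 (interface): integral of density over t in [first body entry,
//                     last structure exit]; 0 if the ray misses the structure.
// [[Rcpp::export(name = ".bev_project_cpp")]]
NumericVector bev_project_cpp(NumericVector density, IntegerVector dims,
                              NumericVector spacing, NumericVector origin,
                              NumericVector source, NumericMatrix pixels,
                              LogicalVector mask, LogicalVector body,
                              int mode) {
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double src[3] = {source[0], source[1], source[2]};
  int np = pixels.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double dir[3], nrm = 0.0;
    for (int a = 0; a < 3; ++a) {
      dir[a] = pixels(p, a) - src[a];
      nrm += dir[a] * dir[a];
    }
    nrm = std::sqrt(nrm);
    for (int a = 0; a < 3; ++a) dir[a] /= nrm;
    std::vector<Seg> segs = traverse_grid(d, sp, org, src, dir);
    double val = 0.0;
    if (mode == 0) {
      for (size_t i = 0; i < segs.size(); ++i)
        if (mask[segs[i].idx]) val += density[segs[i].idx] * (segs[i].t1 - segs[i].t0);
    } else {
      double tA = NA_REAL, tB = NA_REAL;
      for (size_t i = 0; i < segs.size(); ++i) {
        if (ISNA(tA) && body[segs[i].idx]) tA = segs[i].t0;
        if (mask[segs[i].idx]) tB = segs[i].t1;
      }
      if (!ISNA(tA) && !ISNA(tB) && tB > tA) {
        for (size_t i = 0; i < segs.size(); ++i) {
          double a0 = segs[i].t0 > tA ? segs[i].t0 : tA;
          double a1 = segs[i].t1 < tB ? segs[i].t1 : tB;
          if (a1 > a0) val += density[segs[i].idx] * (a1 - a0);
        }
      }
    }
    out[p] = val;
  }
  return out;
}

// Divergent-ray dose deposition: one ray per fluence pixel, primary dose
// fluence * exp(-mu * radiological depth) * (SAD / r)^2 evaluated at each
// traversed voxel midpoint; deposition gated on density >= min_density so
// dose stays confined to tissue. Lateral scatter is applied afterwards.
// [[Rcpp::export(name = ".deposit_dose_cpp")]]
NumericVector deposit_dose_cpp(NumericVector density, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericVector source, NumericMatrix pixels,
                               NumericVector fluence, double mu, double sad,
                               double min_density) {
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double src[3] = {source[0], source[1], source[2]};
  NumericVector dose(density.size());
  int np = pixels.nrow();
  for (int p = 0; p < np; ++p) {
    double f = fluence[p];
    if (f == 0.0) continue;
    double dir[3], nrm = 0.0;
    for (int a = 0; a < 3; ++a) {
      dir[a] = pixels(p, a) - src[a];
      nrm += dir[a] * dir[a];
    }
    nrm = std::sqrt(nrm);
    for (int a = 0; a < 3; ++a) dir[a] /= nrm;
    std::vector<Seg> segs = traverse_grid(d, sp, org, src, dir);
    double rad = 0.0;
    for (size_t i = 0; i < segs.size(); ++i) {
      double len = segs[i].t1 - segs[i].t0;
      double rho = density[segs[i].idx];
      double mid_rad = rad + 0.5 * rho * len;
      if (rho >= min_density) {
        double tm = 0.5 * (segs[i].t0 + segs[i].t1);
        double isq = sad / tm;
        dose[segs[i].idx] += f * std::exp(-mu * mid_rad) * isq * isq;
      }
      rad += rho * len;
    }
  }
  return dose;
}

// Separable 3D Gaussian convolution, zero padding, kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".gauss_blur3_cpp")]]
NumericVector gauss_blur3_cpp(NumericVector arr, IntegerVector dims,
                              NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> b(a.size());
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (i * i) / (s * s));
      ksum += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= ksum;
    int n = sizes[ax], st = strides[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int n1 = sizes[o1], n2 = sizes[o2];
    int st1 = strides[o1], st2 = strides[o2];
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        int base = i1 * st1 + i2 * st2;
        for (int i = 0; i < n; ++i) {
          double v = 0.0;
          int lo = i - r < 0 ? 0 : i - r;
          int hi = i + r >= n ? n - 1 : i + r;
          for (int j = lo; j <= hi; ++j) v += a[base + j * st] * k[j - i + r];
          b[base + i * st] = v;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

static double interp2(const double* ref, int nx, int ny, double sx, double sy,
                      double x, double y, bool* ok) {
  double fx = x / sx, fy = y / sy;
  if (fx < 0 || fy < 0 || fx > nx - 1 || fy > ny - 1) {
    *ok = false;
    return 0.0;
  }
  *ok = true;
  int i = (int)std::floor(fx), j = (int)std::floor(fy);
  if (i >= nx - 1) i = nx - 2;
  if (j >= ny - 1) j = ny - 2;
  if (nx == 1) i = 0;
  if (ny == 1) j = 0;
  double ax = fx - i, ay = fy - j;
  int i1 = (nx == 1) ? i : i + 1;
  int j1 = (ny == 1) ? j : j + 1;
  double v00 = ref[i + nx * j], v10 = ref[i1 + nx * j];
  double v01 = ref[i + nx * j1], v11 = ref[i1 + nx * j1];
  return v00 * (1 - ax) * (1 - ay) + v10 * ax * (1 - ay) +
         v01 * (1 - ax) * ay + v11 * ax * ay;
}

// 2D gamma with exhaustive interpolated search on the reference grid.
// Grids share the physical position of their first pixel center at (0, 0).
// dose_crit_abs used in global mode; local mode uses local_frac * ref value.
// Points with eval dose < thresh_abs get NA.
// [[Rcpp::export(name = ".gamma2d_cpp")]]
NumericVector gamma2d_cpp(NumericVector ref, IntegerVector rdims,
                          NumericVector rspacing, NumericVector ev,
                          IntegerVector edims, NumericVector espacing,
                          double dose_crit_abs, double dist_mm,
                          double search_mm, double step_mm, bool local,
                          double local_frac, double thresh_abs) {
  int rnx = rdims[0], rny = rdims[1];
  int enx = edims[0], eny = edims[1];
  double rsx = rspacing[0], rsy = rspacing[1];
  double esx = espacing[0], esy = espacing[1];
  NumericVector out(ev.size());
  int ns = (int)std::floor(search_mm / step_mm);
  for (int j = 0; j < eny; ++j) {
    for (int i = 0; i < enx; ++i) {
      double de = ev[i + enx * j];
      if (de < thresh_abs) {
        out[i + enx * j] = NA_REAL;
        continue;
      }
      double px = i * esx, py = j * esy;
      double best = std::numeric_limits<double>::infinity();
      for (int oj = -ns; oj <= ns; ++oj) {
        double dy = oj * step_mm;
        for (int oi = -ns; oi <= ns; ++oi) {
          double dx = oi * step_mm;
          double r2 = dx * dx + dy * dy;
          if (r2 > search_mm * search_mm) continue;
          double distterm = r2 / (dist_mm * dist_mm);
          if (distterm >= best) continue;
          bool ok;
          double dr = interp2(ref.begin(), rnx, rny, rsx, rsy, px + dx, py + dy, &ok);
          if (!ok) continue;
          double crit = local ? local_frac * dr : dose_crit_abs;
          if (crit <= 0) continue;
          double dd = (de - dr) / crit;
          double g2 = dd * dd + distterm;
          if (g2 < best) best = g2;
        }
      }
      out[i + enx * j] = std::isfinite(best) ? std::sqrt(best) : NA_REAL;
    }
  }
  return out;
}

static double interp3(const double* ref, const int* n, const double* s,
                      const double* p, bool* ok) {
  double f[3];
  int i0[3], i1[3];
  double a[3];
  for (int ax = 0; ax < 3; ++ax) {
    f[ax] = p[ax] / s[ax];
    if (f[ax] < 0 || f[ax] > n[ax] - 1) {
      *ok = false;
      return 0.0;
    }
    i0[ax] = (int)std::floor(f[ax]);
    if (i0[ax] >= n[ax] - 1) i0[ax] = n[ax] > 1 ? n[ax] - 2 : 0;
    i1[ax] = (n[ax] == 1) ? i0[ax] : i0[ax] + 1;
    a[ax] = f[ax] - i0[ax];
  }
  *ok = true;
  double v = 0.0;
  for (int c = 0; c < 8; ++c) {
    int ix = (c & 1) ? i1[0] : i0[0];
    int iy = (c & 2) ? i1[1] : i0[1];
    int iz = (c & 4) ? i1[2] : i0[2];
    double w = ((c & 1) ? a[0] : 1 - a[0]) * ((c & 2) ? a[1] : 1 - a[1]) *
               ((c & 4) ? a[2] : 1 - a[2]);
    v += w * ref[ix + n[0] * (iy + n[1] * iz)];
  }
  return v;
}

// [[Rcpp::export(name = ".gamma3d_cpp")]]
NumericVector gamma3d_cpp(NumericVector ref, IntegerVector rdims,
                          NumericVector rspacing, NumericVector ev,
                          IntegerVector edims, NumericVector espacing,
                          double dose_crit_abs, double dist_mm,
                          double search_mm, double step_mm, bool local,
                          double local_frac, double thresh_abs) {
  int rn[3] = {rdims[0], rdims[1], rdims[2]};
  int en[3] = {edims[0], edims[1], edims[2]};
  double rs[3] = {rspacing[0], rspacing[1], rspacing[2]};
  double es[3] = {espacing[0], espacing[1], espacing[2]};
  NumericVector out(ev.size());
  int ns = (int)std::floor(search_mm / step_mm);
  for (int k = 0; k < en[2]; ++k) {
    for (int j = 0; j < en[1]; ++j) {
      for (int i = 0; i < en[0]; ++i) {
        int lin = i + en[0] * (j + en[1] * k);
        double de = ev[lin];
        if (de < thresh_abs) {
          out[lin] = NA_REAL;
          continue;
        }
        double p0[3] = {i * es[0], j * es[1], k * es[2]};
        double best = std::numeric_limits<double>::infinity();
        for (int ok_ = -ns; ok_ <= ns; ++ok_) {
          for (int oj = -ns; oj <= ns; ++oj) {
            for (int oi = -ns; oi <= ns; ++oi) {
              double dx = oi * step_mm, dy = oj * step_mm, dz = ok_ * step_mm;
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 > search_mm * search_mm) continue;
              double distterm = r2 / (dist_mm * dist_mm);
              if (distterm >= best) continue;
              double pq[3] = {p0[0] + dx, p0[1] + dy, p0[2] + dz};
              bool ok;
              double dr = interp3(ref.begin(), rn, rs, pq, &ok);
              if (!ok) continue;
              double crit = local ? local_frac * dr : dose_crit_abs;
              if (crit <= 0) continue;
              double dd = (de - dr) / crit;
              double g2 = dd * dd + distterm;
              if (g2 < best) best = g2;
            }
          }
        }
        out[lin] = std::isfinite(best) ? std::sqrt(best) : NA_REAL;
      }
    }
  }
  return out;
}
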