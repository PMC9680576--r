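#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Siddon / Amanatides-Woo voxel traversal.
//
// The volume is a (nx, ny, nz) grid of linear attenuation coefficients
// (1/mm). Voxel (0,0,0) is centered at `origin`; `lower` below denotes the
// outer corner of that voxel (origin - spacing/2). The traversal visits each
// voxel exactly once with its exact chord length, which is the radiological
// path integral Siddon's parametric method computes.
// ---------------------------------------------------------------------------

static double ray_path(const double* mu,
                       const int n[3], const double sp[3], const double lo[3],
                       const double p0[3], const double p1[3]) {
  double dir[3], t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) dir[a] = p1[a] - p0[a];
  const double len = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
  if (len <= 0.0) return 0.0;

  // clip [t0, t1] against the volume bounding box
  for (int a = 0; a < 3; ++a) {
    const double hi = lo[a] + n[a] * sp[a];
    if (std::fabs(dir[a]) < 1e-12) {
      if (p0[a] <= lo[a] || p0[a] >= hi) return 0.0;
    } else {
      double ta = (lo[a] - p0[a]) / dir[a];
      double tb = (hi  - p0[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return 0.0;

  // entry voxel
  int idx[3], step[3];
  double tNext[3], tDelta[3];
  const double eps = 1e-9;
  for (int a = 0; a < 3; ++a) {
    double pa = p0[a] + (t0 + eps) * dir[a];
    int i = (int)std::floor((pa - lo[a]) / sp[a]);
    if (i < 0) i = 0;
    if (i >= n[a]) i = n[a] - 1;
    idx[a] = i;
    if (dir[a] > 1e-12) {
      step[a] = 1;
      tDelta[a] = sp[a] / dir[a];
      tNext[a] = (lo[a] + (i + 1) * sp[a] - p0[a]) / dir[a];
    } else if (dir[a] < -1e-12) {
      step[a] = -1;
      tDelta[a] = -sp[a] / dir[a];
      tNext[a] = (lo[a] + i * sp[a] - p0[a]) / dir[a];
    } else {
      step[a] = 0;
      tDelta[a] = std::numeric_limits<double>::infinity();
      tNext[a] = std::numeric_limits<double>::infinity();
    }
  }

  double t = t0, path = 0.0;
  const long nxy = (long)n[0] * n[1];
  while (t < t1 - 1e-12) {
    int amin = 0;
    if (tNext[1] < tNext[amin]) amin = 1;
    if (tNext[2] < tNext[amin]) amin = 2;
    double tn = tNext[amin] < t1 ? tNext[amin] : t1;
    const double seg = (tn - t) * len;
    if (seg > 0.0)
      path += mu[idx[0] + (long)n[0] * idx[1] + nxy * idx[2]] * seg;
    t = tn;
    if (tNext[amin] >= t1) break;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= n[amin]) break;
    tNext[amin] += tDelta[amin];
  }
  return path;
}

// [[Rcpp::export]]
double cpp_ray_path(NumericVector mu, IntegerVector dims, NumericVector spacing,
                    NumericVector origin, NumericVector p0, NumericVector p1) {
  int n[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double lo[3], a0[3], a1[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * sp[a];
    a0[a] = p0[a];
    a1[a] = p1[a];
  }
  return ray_path(REAL(mu), n, sp, lo, a0, a1);
}

// Radiological path image: one ray per detector pixel. Pixel (i, j) maps to
// the isocenter-plane point  q = iso + x[i]*u + y[j]*v ; the physical
// detector point is  src + (q - src) * mag  with mag = SID/SAD.
// [[Rcpp::export]]
NumericMatrix cpp_drr_path(NumericVector mu, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericVector src, NumericVector iso,
                           NumericVector u, NumericVector v,
                           NumericVector px, NumericVector py, double mag) {
  int n[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double lo[3], s[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * sp[a];
    s[a] = src[a];
  }
  const int nx = px.size(), ny = py.size();
  NumericMatrix out(nx, ny);
  const double* muv = REAL(mu);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double q[3], p1[3];
      for (int a = 0; a < 3; ++a) {
        q[a] = iso[a] + px[i] * u[a] + py[j] * v[a];
        p1[a] = s[a] + (q[a] - s[a]) * mag;
      }
      out(i, j) = ray_path(muv, n, sp, lo, s, p1);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mutual information.
// ---------------------------------------------------------------------------

// Plain joint-histogram MI in nats; each image binned over its own range.
// [[Rcpp::export]]
double cpp_mi_plain(NumericMatrix a, NumericMatrix b, int nbins) {
  const int npx = a.size();
  if (npx != b.size()) stop("image size mismatch");
  double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
  const double* av = REAL(a);
  const double* bv = REAL(b);
  for (int k = 0; k < npx; ++k) {
    if (av[k] < amin) amin = av[k];
    if (av[k] > amax) amax = av[k];
    if (bv[k] < bmin) bmin = bv[k];
    if (bv[k] > bmax) bmax = bv[k];
  }
  const double ascale = amax > amin ? (nbins - 1e-9) / (amax - amin) : 0.0;
  const double bscale = bmax > bmin ? (nbins - 1e-9) / (bmax - bmin) : 0.0;
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  for (int k = 0; k < npx; ++k) {
    int ia = (int)((av[k] - amin) * ascale);
    int ib = (int)((bv[k] - bmin) * bscale);
    joint[ia + (size_t)nbins * ib] += 1.0;
  }
  std::vector<double> pa(nbins, 0.0), pb(nbins, 0.0);
  const double inv = 1.0 / npx;
  for (int ib = 0; ib < nbins; ++ib)
    for (int ia = 0; ia < nbins; ++ia) {
      const double p = joint[ia + (size_t)nbins * ib] * inv;
      pa[ia] += p;
      pb[ib] += p;
    }
  double mi = 0.0;
  for (int ib = 0; ib < nbins; ++ib)
    for (int ia = 0; ia < nbins; ++ia) {
      const double p = joint[ia + (size_t)nbins * ib] * inv;
      if (p > 0.0) mi += p * std::log(p / (pa[ia] * pb[ib]));
    }
  return mi;
}

// ---------------------------------------------------------------------------
// Translation registration.
//
// Maximizes MI(fixed(x), moving(x + t)) over the in-plane translation t
// (pixels), so the returned t is the displacement of the moving image's
// content relative to the fixed image. Deterministic coarse-to-fine search:
// integer-pixel grid (stride 2 then 1), then step-halving local pattern
// refinement with subpixel resampling. The joint histogram uses linear
// spreading of both intensities across adjacent bins so MI varies smoothly
// with t.
//
// Sampled joint-histogram MI carries a ~1-px-periodic "pixel locking"
// perturbation that biases subpixel optima by up to ~0.1 px. The accurate
// mode therefore evaluates the final stages on the half-pixel supersampled
// grid (both images resampled with interpolating cubic B-splines): the
// sample set then holds both phases of the locking term in equal measure
// at every location and its fundamental cancels.
// ---------------------------------------------------------------------------

static inline double b3_w(double t, int k) {
  // cubic B-spline basis weights for taps k = -1, 0, 1, 2 at offset t
  const double u = 1.0 - t;
  switch (k) {
    case -1: return u * u * u / 6.0;
    case 0:  return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
    case 1:  return (4.0 - 6.0 * u * u + 3.0 * u * u * u) / 6.0;
    default: return t * t * t / 6.0;
  }
}

// In-place separable prefilter turning samples into interpolating cubic
// B-spline coefficients (single pole z = sqrt(3) - 2, per-pass gain 6).
static void bspline_prefilter(std::vector<double>& c, int nx, int ny) {
  const double z = std::sqrt(3.0) - 2.0;
  const int horizon = 32;
  auto filt1 = [&](double* s, int n, long stride) {
    if (n < 2) return;
    double sum = s[0];
    double zk = z;
    for (int k = 1; k < std::min(n, horizon); ++k) {
      sum += zk * s[(long)k * stride];
      zk *= z;
    }
    s[0] = sum;
    for (int i = 1; i < n; ++i)
      s[(long)i * stride] += z * s[(long)(i - 1) * stride];
    s[(long)(n - 1) * stride] =
      (z / (z * z - 1.0)) *
      (s[(long)(n - 1) * stride] + z * s[(long)(n - 2) * stride]);
    for (int i = n - 2; i >= 0; --i)
      s[(long)i * stride] =
        z * (s[(long)(i + 1) * stride] - s[(long)i * stride]);
    for (int i = 0; i < n; ++i) s[(long)i * stride] *= 6.0;
  };
  for (int j = 0; j < ny; ++j) filt1(c.data() + (long)j * nx, nx, 1);
  for (int i = 0; i < nx; ++i) filt1(c.data() + i, ny, nx);
}

static inline double bspline_sample(const double* c, int nx, int ny,
                                    double xs, double ys, bool& ok) {
  const int ix = (int)std::floor(xs);
  const int jy = (int)std::floor(ys);
  if (ix - 1 < 0 || ix + 2 >= nx || jy - 1 < 0 || jy + 2 >= ny) {
    ok = false;
    return 0.0;
  }
  ok = true;
  const double fx = xs - ix, fy = ys - jy;
  double wx[4], wy[4];
  for (int k = 0; k < 4; ++k) {
    wx[k] = b3_w(fx, k - 1);
    wy[k] = b3_w(fy, k - 1);
  }
  double acc = 0.0;
  for (int ky = 0; ky < 4; ++ky) {
    const double* row = c + (ix - 1) + (long)nx * (jy - 1 + ky);
    acc += wy[ky] * (wx[0] * row[0] + wx[1] * row[1] +
                     wx[2] * row[2] + wx[3] * row[3]);
  }
  return acc;
}

struct RegWork {
  int nx, ny, nbins;
  int stride;                  // pixel subsampling for modes 0/1
  int ixlo, ixhi, iylo, iyhi;  // refinement sample window (base pixels)
  int min_samples;
  const double* mv;            // moving intensities
  double mmin, mscale;         // moving -> continuous bin coordinate
  std::vector<double> fb;      // fixed bins on the base grid
  std::vector<double> fb2;     // fixed bins on the half-px grid (-1 = n/a)
  std::vector<double> fc;      // fixed B-spline coefficients (mode 2)
  std::vector<double> mc;      // moving B-spline coefficients (mode 2)
  double fmin, fscale;
  std::vector<double> joint, pa, pb;
  bool accurate;
};

static void reg_setup(RegWork& w, const double* fv, const double* mvv,
                      int nx, int ny, int nbins, bool accurate,
                      int min_samples, int stride, int margin,
                      double fmin, double fmax, double mmin, double mmax) {
  w.nx = nx; w.ny = ny; w.nbins = nbins;
  w.stride = stride < 1 ? 1 : stride;
  w.min_samples = min_samples;
  w.mv = mvv;
  w.mmin = mmin;
  w.mscale = (nbins - 1e-6) / (mmax - mmin);
  const long npx = (long)nx * ny;
  const double fscale = (nbins - 1e-6) / (fmax - fmin);
  w.fb.resize(npx);
  for (long k = 0; k < npx; ++k) w.fb[k] = (fv[k] - fmin) * fscale;
  w.joint.assign((size_t)nbins * nbins, 0.0);
  w.pa.assign(nbins, 0.0);
  w.pb.assign(nbins, 0.0);
  w.accurate = accurate;
  w.ixlo = 0; w.ixhi = nx - 1; w.iylo = 0; w.iyhi = ny - 1;
  (void)margin;
  if (!accurate) return;
  w.mc.assign(mvv, mvv + npx);
  bspline_prefilter(w.mc, nx, ny);
  w.fc.assign(fv, fv + npx);
  bspline_prefilter(w.fc, nx, ny);
  w.fmin = fmin;
  w.fscale = fscale;
}

// Fix the refinement sample window around the coarse optimum (t0x, t0y):
// base pixels whose fixed and moving samples stay inside cubic support
// for every t within `exc` pixels of t0, so the sample set — and hence
// the MI objective — does not change with the candidate shift. Fills the
// cached fixed-bin half-pixel grid over that window.
static void reg_refine_setup(RegWork& w, double t0x, double t0y,
                             double exc) {
  const int nx = w.nx, ny = w.ny;
  auto win1 = [&](double t0, int n, int& lo, int& hi) {
    lo = (int)std::ceil(std::max(2.0, 1.0 - (t0 - exc)));
    hi = (int)std::floor(std::min((double)n - 3, n - 3 - (t0 + exc)));
    if (hi - lo < 4) { lo = 2; hi = n - 3; }  // degenerate: keep support
  };
  win1(t0x, nx, w.ixlo, w.ixhi);
  win1(t0y, ny, w.iylo, w.iyhi);
  if (!w.accurate) return;
  const int n2x = 2 * nx - 1, n2y = 2 * ny - 1;
  w.fb2.assign((size_t)n2x * n2y, -1.0);
  const double bmax = w.nbins - 1e-6;
  for (int j2 = 2 * w.iylo; j2 <= 2 * w.iyhi; ++j2) {
    const double yj = 0.5 * j2;
    for (int i2 = 2 * w.ixlo; i2 <= 2 * w.ixhi; ++i2) {
      bool ok;
      const double f = bspline_sample(w.fc.data(), nx, ny, 0.5 * i2, yj,
                                      ok);
      if (!ok) continue;
      double bf = (f - w.fmin) * w.fscale;
      if (bf < 0.0) bf = 0.0;
      if (bf > bmax) bf = bmax;
      w.fb2[i2 + (size_t)n2x * j2] = bf;
    }
  }
}

// mode: 0 = integer shift, 1 = bilinear, 2 = supersampled cubic B-spline
static double mi_eval(RegWork& w, double tx, double ty, int mode) {
  std::fill(w.joint.begin(), w.joint.end(), 0.0);
  const int nx = w.nx, ny = w.ny, nb = w.nbins;
  double total = 0.0;
  const double bmax = nb - 1e-6;
  double* J = w.joint.data();

  if (mode == 2) {
    const int n2x = 2 * nx - 1, n2y = 2 * ny - 1;
    for (int j2 = 0; j2 < n2y; ++j2) {
      const double ys = 0.5 * j2 + ty;
      for (int i2 = 0; i2 < n2x; ++i2) {
        const double bf = w.fb2[i2 + (size_t)n2x * j2];
        if (bf < 0.0) continue;
        bool ok;
        const double m = bspline_sample(w.mc.data(), nx, ny,
                                        0.5 * i2 + tx, ys, ok);
        if (!ok) continue;
        double bm = (m - w.mmin) * w.mscale;
        if (bm < 0.0) bm = 0.0;
        if (bm > bmax) bm = bmax;
        const int f0 = (int)bf, m0 = (int)bm;
        const double wf = bf - f0, wmw = bm - m0;
        const int f1 = f0 + 1 < nb ? f0 + 1 : f0;
        const int m1 = m0 + 1 < nb ? m0 + 1 : m0;
        J[f0 + (size_t)nb * m0] += (1 - wf) * (1 - wmw);
        J[f1 + (size_t)nb * m0] += wf * (1 - wmw);
        J[f0 + (size_t)nb * m1] += (1 - wf) * wmw;
        J[f1 + (size_t)nb * m1] += wf * wmw;
        total += 1.0;
      }
    }
  } else {
    const int st = w.stride;
    const int jlo = (mode == 1) ? w.iylo : 0;
    const int jhi = (mode == 1) ? w.iyhi : ny - 1;
    const int ilo = (mode == 1) ? w.ixlo : 0;
    const int ihi = (mode == 1) ? w.ixhi : nx - 1;
    for (int j = jlo; j <= jhi; j += st) {
      const double ym = j + ty;
      const int jy = (int)std::floor(ym);
      const double fy = ym - jy;
      if (mode == 0) { if (jy < 0 || jy >= ny) continue; }
      else { if (jy < 0 || jy + 1 >= ny) continue; }
      for (int i = ilo; i <= ihi; i += st) {
        double m;
        const double xm = i + tx;
        const int ix = (int)std::floor(xm);
        if (mode == 0) {
          if (ix < 0 || ix >= nx) continue;
          m = w.mv[ix + (long)nx * jy];
        } else {
          if (ix < 0 || ix + 1 >= nx) continue;
          const double fx = xm - ix;
          const double* c = w.mv + ix + (long)nx * jy;
          m = (1 - fx) * (1 - fy) * c[0] + fx * (1 - fy) * c[1] +
              (1 - fx) * fy * c[nx] + fx * fy * c[nx + 1];
        }
        const double bf = w.fb[i + (long)nx * j];
        double bm = (m - w.mmin) * w.mscale;
        if (bm < 0.0) bm = 0.0;
        if (bm > bmax) bm = bmax;
        const int f0 = (int)bf, m0 = (int)bm;
        const double wf = bf - f0, wmw = bm - m0;
        const int f1 = f0 + 1 < nb ? f0 + 1 : f0;
        const int m1 = m0 + 1 < nb ? m0 + 1 : m0;
        J[f0 + (size_t)nb * m0] += (1 - wf) * (1 - wmw);
        J[f1 + (size_t)nb * m0] += wf * (1 - wmw);
        J[f0 + (size_t)nb * m1] += (1 - wf) * wmw;
        J[f1 + (size_t)nb * m1] += wf * wmw;
        total += 1.0;
      }
    }
  }
  if (total < w.min_samples) return R_NegInf;

  std::fill(w.pa.begin(), w.pa.end(), 0.0);
  std::fill(w.pb.begin(), w.pb.end(), 0.0);
  const double inv = 1.0 / total;
  for (int ib = 0; ib < nb; ++ib) {
    const double* col = J + (size_t)nb * ib;
    double sum = 0.0;
    for (int ia = 0; ia < nb; ++ia) {
      const double p = col[ia] * inv;
      w.pa[ia] += p;
      sum += p;
    }
    w.pb[ib] = sum;
  }
  double mi = 0.0;
  for (int ib = 0; ib < nb; ++ib) {
    const double* col = J + (size_t)nb * ib;
    const double qb = w.pb[ib];
    if (qb <= 0.0) continue;
    for (int ia = 0; ia < nb; ++ia) {
      const double p = col[ia] * inv;
      if (p > 0.0) mi += p * std::log(p / (w.pa[ia] * qb));
    }
  }
  return mi;
}

static bool reg_ranges(const double* fv, const double* mvv, long npx,
                       double& fmin, double& fmax,
                       double& mmin, double& mmax) {
  fmin = R_PosInf; fmax = R_NegInf; mmin = R_PosInf; mmax = R_NegInf;
  for (long k = 0; k < npx; ++k) {
    if (fv[k] < fmin) fmin = fv[k];
    if (fv[k] > fmax) fmax = fv[k];
    if (mvv[k] < mmin) mmin = mvv[k];
    if (mvv[k] > mmax) mmax = mvv[k];
  }
  // require genuine contrast: numerical noise (e.g. 1e-15 ripples from a
  // filtered constant region) must not count as registrable signal
  const double ftol = 1e-12 * std::max(1.0, std::fabs(fmax));
  const double mtol = 1e-12 * std::max(1.0, std::fabs(mmax));
  return (fmax - fmin) > ftol && (mmax - mmin) > mtol;
}

// [[Rcpp::export]]
NumericVector cpp_mi_at_shifts(NumericMatrix fixed, NumericMatrix moving,
                               NumericVector tx, NumericVector ty,
                               int nbins, int interp, int min_samples) {
  const int nx = fixed.nrow(), ny = fixed.ncol();
  double fmin, fmax, mmin, mmax;
  if (!reg_ranges(REAL(fixed), REAL(moving), (long)nx * ny,
                  fmin, fmax, mmin, mmax))
    stop("constant image");
  RegWork w;
  double tmax = 0.0;
  for (int k = 0; k < tx.size(); ++k) {
    if (std::fabs(tx[k]) > tmax) tmax = std::fabs(tx[k]);
    if (std::fabs(ty[k]) > tmax) tmax = std::fabs(ty[k]);
  }
  reg_setup(w, REAL(fixed), REAL(moving), nx, ny, nbins, interp == 2,
            min_samples, 1, 0, fmin, fmax, mmin, mmax);
  reg_refine_setup(w, 0.0, 0.0, tmax + 0.5);
  NumericVector out(tx.size());
  for (int k = 0; k < tx.size(); ++k)
    out[k] = mi_eval(w, tx[k], ty[k], interp);
  return out;
}

// [[Rcpp::export]]
List cpp_register_translation(NumericMatrix fixed, NumericMatrix moving,
                              double pitch, double bound_mm, double tol_mm,
                              int nbins, int interp, int min_samples,
                              int stride) {
  const int nx = fixed.nrow(), ny = fixed.ncol();
  if (moving.nrow() != nx || moving.ncol() != ny)
    stop("fixed and moving images must share dimensions");
  double fmin, fmax, mmin, mmax;
  if (!reg_ranges(REAL(fixed), REAL(moving), (long)nx * ny,
                  fmin, fmax, mmin, mmax)) {
    return List::create(_["dx_mm"] = NA_REAL, _["dy_mm"] = NA_REAL,
                        _["mi"] = NA_REAL, _["iterations"] = 0,
                        _["converged"] = false);
  }
  const int B = (int)std::ceil(bound_mm / pitch);
  RegWork w;
  reg_setup(w, REAL(fixed), REAL(moving), nx, ny, nbins, interp == 2,
            min_samples, stride, 0, fmin, fmax, mmin, mmax);
  int evals = 0;
  double best = R_NegInf, bx = 0.0, by = 0.0;

  // integer coarse search, stride 2 when the bound is wide
  const int cstride = B >= 4 ? 2 : 1;
  for (int ty = -B; ty <= B; ty += cstride)
    for (int tx = -B; tx <= B; tx += cstride) {
      const double mi = mi_eval(w, tx, ty, 0);
      ++evals;
      if (mi > best) { best = mi; bx = tx; by = ty; }
    }
  if (!R_finite(best)) {
    return List::create(_["dx_mm"] = NA_REAL, _["dy_mm"] = NA_REAL,
                        _["mi"] = NA_REAL, _["iterations"] = evals,
                        _["converged"] = false);
  }
  if (cstride > 1) {
    const double cx = bx, cy = by;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        const double tx = cx + dx, ty = cy + dy;
        if (std::fabs(tx) > B || std::fabs(ty) > B) continue;
        const double mi = mi_eval(w, tx, ty, 0);
        ++evals;
        if (mi > best) { best = mi; bx = tx; by = ty; }
      }
  }

  // subpixel refinement: step-halving pattern search; the accurate mode
  // runs a cheap bilinear stage first, then the supersampled estimator
  // for the final sub-eighth-pixel stages. The sample window is fixed
  // around the coarse optimum and the search clamped to its validity
  // region, so the objective is continuous across the whole stage.
  const double exc = 2.5;
  const double t0x = bx, t0y = by;
  reg_refine_setup(w, t0x, t0y, exc);
  const double tol_px = tol_mm / pitch;
  const int max_evals = 2000;
  auto refine = [&](int mode, double step0, double tol_stage) {
    best = mi_eval(w, bx, by, mode);
    ++evals;
    double step = step0;
    while (step >= tol_stage && evals < max_evals) {
      double nbx = bx, nby = by, nbest = best;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          const double tx = bx + dx * step, ty = by + dy * step;
          if (std::fabs(tx) > B || std::fabs(ty) > B) continue;
          if (std::fabs(tx - t0x) > exc || std::fabs(ty - t0y) > exc)
            continue;
          const double mi = mi_eval(w, tx, ty, mode);
          ++evals;
          if (mi > nbest) { nbest = mi; nbx = tx; nby = ty; }
        }
      if (nbest > best) { best = nbest; bx = nbx; by = nby; }
      else step *= 0.5;
    }
  };
  if (interp == 2) {
    refine(1, 0.5, std::max(0.125, tol_px));
    refine(2, 0.125, tol_px);
  } else {
    refine(interp, 0.5, tol_px);
  }

  return List::create(_["dx_mm"] = bx * pitch, _["dy_mm"] = by * pitch,
                      _["mi"] = best, _["iterations"] = evals,
                      _["converged"] = true);
}

static inline double cr_w(double t, int k) {
  // Catmull-Rom weights for taps k = -1, 0, 1, 2 at fractional offset t
  switch (k) {
    case -1: return ((-0.5 * t + 1.0) * t - 0.5) * t;
    case 0:  return (1.5 * t - 2.5) * t * t + 1.0;
    case 1:  return ((-1.5 * t + 2.0) * t + 0.5) * t;
    default: return (0.5 * t - 0.5) * t * t;
  }
}

// Catmull-Rom resampled translation of an image: out(x) = img(x - d), i.e.
// the content moves by +d pixels. Out-of-support samples fall back to the
// nearest edge value. Used as an alternative to Fourier shifting.
// [[Rcpp::export]]
NumericMatrix cpp_shift_cubic(NumericMatrix img, double dx, double dy) {
  const int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(nx, ny);
  const double* v = REAL(img);
  for (int j = 0; j < ny; ++j) {
    double ys = j - dy;
    if (ys < 0) ys = 0;
    if (ys > ny - 1) ys = ny - 1;
    int jy = (int)std::floor(ys);
    if (jy > ny - 2) jy = ny - 2;
    const double fy = ys - jy;
    double wy[4];
    for (int k = 0; k < 4; ++k) wy[k] = cr_w(fy, k - 1);
    for (int i = 0; i < nx; ++i) {
      double xs = i - dx;
      if (xs < 0) xs = 0;
      if (xs > nx - 1) xs = nx - 1;
      int ix = (int)std::floor(xs);
      if (ix > nx - 2) ix = nx - 2;
      const double fx = xs - ix;
      double wx[4];
      for (int k = 0; k < 4; ++k) wx[k] = cr_w(fx, k - 1);
      double acc = 0.0;
      for (int ky = 0; ky < 4; ++ky) {
        int jj = jy - 1 + ky;
        if (jj < 0) jj = 0;
        if (jj > ny - 1) jj = ny - 1;
        double rowacc = 0.0;
        for (int kx = 0; kx < 4; ++kx) {
          int ii = ix - 1 + kx;
          if (ii < 0) ii = 0;
          if (ii > nx - 1) ii = nx - 1;
          rowacc += wx[kx] * v[ii + (long)nx * jj];
        }
        acc += wy[ky] * rowacc;
      }
      out(i, j) = acc;
    }
  }
  return out;
}
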