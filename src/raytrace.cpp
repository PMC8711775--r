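// Ray-tracing core for compound-eye SPECT aperture modelling.
//
// All geometry is evaluated in the local frame of a micro-camera element
// (MCE): origin at the aperture centre, +w along the module axis toward the
// detector, u/v spanning the aperture plane.  The tungsten collimator is the
// slab w in [-t_l, +t_u] minus an open channel whose cross-section is a
// piecewise linear/quadratic function of w, so the chord of a straight ray
// inside tungsten has a closed form: the channel intersection is an interval
// list obtained from linear and quadratic constraints in the ray parameter.
// A fixed-step midpoint marcher over the same solid is kept as an
// independent oracle.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double EPS_DIR = 1e-12;

// ---------------------------------------------------------------------------
// aperture parameter block (fixed-width row of a numeric matrix)
// [0] kind: 0 lofthole, 1 micro_slit, 2 micro_ring
// [1] t_u  [2] t_l  [3] mu_w
// lofthole: [4] d/2            [5] tan_alpha [6] tan_beta
// slit:     [4] w/2  [5] l/2   [6] tan_as [7] tan_bs [8] tan_al [9] tan_bl
//           [10] theta (rad)
// ring:     [4] r_o  [5] r_i   [6] tan_alpha [7] tan_beta
// [11] half-module width (mm), used to clip the slit's upper channel
// ---------------------------------------------------------------------------

static const int AP_NPAR = 12;

// ------------------------- interval list ----------------------------------

struct Ivls {
  double lo[6], hi[6];
  int n;
  void init(double a, double b) { n = 1; lo[0] = a; hi[0] = b; }
  double total() const {
    double t = 0;
    for (int i = 0; i < n; ++i) t += hi[i] - lo[i];
    return t;
  }
};

// keep s with s <= r (dir=+1) or s >= r (dir=-1)
static inline void keep_halfline(Ivls &v, double r, int dir) {
  int m = 0;
  for (int i = 0; i < v.n; ++i) {
    double a = v.lo[i], b = v.hi[i];
    if (dir > 0) { if (b > r) b = r; }
    else         { if (a < r) a = r; }
    if (b > a) { v.lo[m] = a; v.hi[m] = b; ++m; }
  }
  v.n = m;
}

// keep s with c0 + c1*s <= 0
static inline void clip_linear(Ivls &v, double c0, double c1) {
  if (std::fabs(c1) < 1e-14) {
    if (c0 > 0) v.n = 0;
    return;
  }
  double r = -c0 / c1;
  keep_halfline(v, r, c1 > 0 ? +1 : -1);
}

static inline void keep_range(Ivls &v, double r1, double r2) {
  keep_halfline(v, r1, -1);
  keep_halfline(v, r2, +1);
}

// remove the open range (r1, r2)
static inline void subtract_range(Ivls &v, double r1, double r2) {
  Ivls out;
  out.n = 0;
  for (int i = 0; i < v.n; ++i) {
    double a = v.lo[i], b = v.hi[i];
    double a1 = a, b1 = std::min(b, r1);
    double a2 = std::max(a, r2), b2 = b;
    if (b1 > a1 && out.n < 6) { out.lo[out.n] = a1; out.hi[out.n] = b1; ++out.n; }
    if (b2 > a2 && out.n < 6) { out.lo[out.n] = a2; out.hi[out.n] = b2; ++out.n; }
  }
  v = out;
}

// keep s with A s^2 + B s + C <= 0
static inline void clip_quad(Ivls &v, double A, double B, double C) {
  if (std::fabs(A) < 1e-13) { clip_linear(v, C, B); return; }
  double disc = B * B - 4.0 * A * C;
  if (A > 0) {
    if (disc <= 0) { v.n = 0; return; }
    double sq = std::sqrt(disc);
    keep_range(v, (-B - sq) / (2 * A), (-B + sq) / (2 * A));
  } else {
    if (disc <= 0) return;  // concave, negative everywhere
    double sq = std::sqrt(disc);
    double r1 = (-B + sq) / (2 * A), r2 = (-B - sq) / (2 * A);  // r1 < r2
    subtract_range(v, r1, r2);
  }
}

// ------------------------- channel constraints ----------------------------

// | g . p_xy(s) | <= m0 + m1 * w(s)
static inline void clip_abs_linear(Ivls &v, double gP, double gD,
                                   double m0, double m1,
                                   double Pz, double dz) {
  double h0 = m0 + m1 * Pz, h1 = m1 * dz;
  clip_linear(v, gP - h0, gD - h1);
  clip_linear(v, -gP - h0, -gD - h1);
}

// r(s)^2 <= (e0 + e1 s)^2   (disc of linearly varying radius)
static inline void clip_disc(Ivls &v, double Pxy2, double PD, double D2,
                             double e0, double e1) {
  clip_quad(v, D2 - e1 * e1, 2.0 * (PD - e0 * e1), Pxy2 - e0 * e0);
}

// r(s)^2 >= (e0 + e1 s)^2   (outside a shrinking/growing plug)
static inline void clip_outside_disc(Ivls &v, double Pxy2, double PD, double D2,
                                     double e0, double e1) {
  clip_quad(v, e1 * e1 - D2, 2.0 * (e0 * e1 - PD), e0 * e0 - Pxy2);
}

// admissible channel length for one w-region [wa, wb] (wa < wb)
static double region_channel_len(const double *ap, const double *P,
                                 const double *D, double sA, double sB,
                                 double wa, double wb) {
  double dz = D[2], Pz = P[2];
  double ra, rb;
  if (std::fabs(dz) < EPS_DIR) {
    if (Pz <= wa || Pz >= wb) return 0.0;
    ra = sA; rb = sB;
  } else {
    double s1 = (wa - Pz) / dz, s2 = (wb - Pz) / dz;
    ra = std::max(std::min(s1, s2), sA);
    rb = std::min(std::max(s1, s2), sB);
    if (rb <= ra) return 0.0;
  }
  Ivls v;
  v.init(ra, rb);

  int kind = (int)ap[0];
  bool lower = wb <= 0.0;  // regions never straddle w = 0
  double Px = P[0], Py = P[1], dx = D[0], dy = D[1];

  if (kind == 0) {  // lofthole: square frustum cut by an expanding disc
    double d2 = ap[4];
    double tn = lower ? ap[5] : ap[6];
    double m1 = lower ? -tn : tn;
    clip_abs_linear(v, Px, dx, d2, m1, Pz, dz);
    clip_abs_linear(v, Py, dy, d2, m1, Pz, dz);
    double Ks = (lower ? -1.0 : 1.0) * M_SQRT2 * tn;  // disc radius d2 + Ks*w
    clip_disc(v, Px * Px + Py * Py, Px * dx + Py * dy, dx * dx + dy * dy,
              d2 + Ks * Pz, Ks * dz);
  } else if (kind == 1) {  // micro-slit
    double w2 = ap[4], l2 = ap[5], th = ap[10];
    double c = std::cos(th), s = std::sin(th);
    // rotated frame coordinates: x' = c x + s y ; y' = -s x + c y
    double gxP = c * Px + s * Py, gxD = c * dx + s * dy;
    double gyP = -s * Px + c * Py, gyD = -s * dx + c * dy;
    if (lower) {
      clip_abs_linear(v, gxP, gxD, w2, -ap[6], Pz, dz);
      clip_abs_linear(v, gyP, gyD, l2, -ap[8], Pz, dz);
    } else {
      clip_abs_linear(v, gxP, gxD, w2, ap[7], Pz, dz);
      clip_abs_linear(v, gyP, gyD, l2, ap[9], Pz, dz);
      double H = ap[11];
      clip_abs_linear(v, Px, dx, H, 0.0, Pz, dz);  // module footprint clip
      clip_abs_linear(v, Py, dy, H, 0.0, Pz, dz);
    }
  } else {  // micro-ring: annulus between outer cone and central plug
    double ro = ap[4], ri = ap[5];
    double tn = lower ? ap[6] : ap[7];
    double Pxy2 = Px * Px + Py * Py, PD = Px * dx + Py * dy,
           D2 = dx * dx + dy * dy;
    double sgn = lower ? -1.0 : 1.0;  // |w| = sgn * w
    // R_out = ro + |w| tn ; R_in = ri - |w| tn (clamped by region split)
    clip_disc(v, Pxy2, PD, D2, ro + sgn * tn * Pz, sgn * tn * dz);
    double Rin0 = ri + (lower ? tn * Pz : -tn * Pz);
    bool plug = (lower ? (wa >= -ri / std::max(tn, 1e-12))
                       : (wb <= ri / std::max(tn, 1e-12)));
    if (plug)
      clip_outside_disc(v, Pxy2, PD, D2, Rin0, (lower ? tn : -tn) * dz);
  }
  return v.total();
}

// chord of the ray segment (length len, unit dir D, origin P) in tungsten
static double tungsten_path_analytic(const double *ap, const double *P,
                                     const double *D, double len) {
  double t_u = ap[1], t_l = ap[2], dz = D[2], Pz = P[2];
  double sA, sB;
  if (std::fabs(dz) < EPS_DIR) {
    if (Pz <= -t_l || Pz >= t_u) return 0.0;
    sA = 0.0; sB = len;
  } else {
    double s1 = (-t_l - Pz) / dz, s2 = (t_u - Pz) / dz;
    sA = std::max(std::min(s1, s2), 0.0);
    sB = std::min(std::max(s1, s2), len);
    if (sB <= sA) return 0.0;
  }
  double chan = 0.0;
  int kind = (int)ap[0];
  if (kind == 2) {  // ring has extra breakpoints where the plug vanishes
    double ri = ap[5];
    double wl = -ri / std::max(ap[6], 1e-12);  // plug foot, lower side
    double wu = ri / std::max(ap[7], 1e-12);   // plug foot, upper side
    double wl0 = std::max(wl, -t_l), wu0 = std::min(wu, t_u);
    if (wl0 > -t_l) chan += region_channel_len(ap, P, D, sA, sB, -t_l, wl0);
    chan += region_channel_len(ap, P, D, sA, sB, wl0, 0.0);
    chan += region_channel_len(ap, P, D, sA, sB, 0.0, wu0);
    if (wu0 < t_u) chan += region_channel_len(ap, P, D, sA, sB, wu0, t_u);
  } else {
    chan += region_channel_len(ap, P, D, sA, sB, -t_l, 0.0);
    chan += region_channel_len(ap, P, D, sA, sB, 0.0, t_u);
  }
  double path = (sB - sA) - chan;
  return path > 0 ? path : 0.0;
}

// ------------------------- point-in-channel (marching oracle) --------------

static inline bool inside_channel(const double *ap, double x, double y,
                                  double wz) {
  int kind = (int)ap[0];
  if (kind == 0) {
    double d2 = ap[4];
    double tn = wz <= 0 ? ap[5] : ap[6];
    double h = d2 + std::fabs(wz) * tn;
    double c = d2 + std::fabs(wz) * M_SQRT2 * tn;
    return std::fabs(x) <= h && std::fabs(y) <= h && x * x + y * y <= c * c;
  } else if (kind == 1) {
    double w2 = ap[4], l2 = ap[5], th = ap[10];
    double cth = std::cos(th), sth = std::sin(th);
    double xr = cth * x + sth * y, yr = -sth * x + cth * y;
    if (wz <= 0)
      return std::fabs(xr) <= w2 + std::fabs(wz) * ap[6] &&
             std::fabs(yr) <= l2 + std::fabs(wz) * ap[8];
    double H = ap[11];
    return std::fabs(xr) <= w2 + wz * ap[7] &&
           std::fabs(yr) <= l2 + wz * ap[9] &&
           std::fabs(x) <= H && std::fabs(y) <= H;
  } else {
    double tn = wz <= 0 ? ap[6] : ap[7];
    double Rout = ap[4] + std::fabs(wz) * tn;
    double Rin = ap[5] - std::fabs(wz) * tn;
    if (Rin < 0) Rin = 0;
    double r2 = x * x + y * y;
    return r2 <= Rout * Rout && r2 >= Rin * Rin;
  }
}

static double tungsten_path_march(const double *ap, const double *P,
                                  const double *D, double len, double step) {
  double t_u = ap[1], t_l = ap[2], dz = D[2], Pz = P[2];
  double sA, sB;
  if (std::fabs(dz) < EPS_DIR) {
    if (Pz <= -t_l || Pz >= t_u) return 0.0;
    sA = 0.0; sB = len;
  } else {
    double s1 = (-t_l - Pz) / dz, s2 = (t_u - Pz) / dz;
    sA = std::max(std::min(s1, s2), 0.0);
    sB = std::min(std::max(s1, s2), len);
    if (sB <= sA) return 0.0;
  }
  double path = 0.0;
  long n = (long)std::ceil((sB - sA) / step);
  double h = (sB - sA) / n;
  for (long i = 0; i < n; ++i) {
    double s = sA + (i + 0.5) * h;
    double x = P[0] + s * D[0], y = P[1] + s * D[1], w = Pz + s * dz;
    if (!inside_channel(ap, x, y, w)) path += h;
  }
  return path;
}

// ------------------------- exported ray utilities --------------------------

// [[Rcpp::export]]
NumericVector cpp_tungsten_path(NumericMatrix origin, NumericMatrix target,
                                NumericVector ap, int method, double step) {
  int n = origin.nrow();
  NumericVector out(n);
  std::vector<double> a(ap.begin(), ap.end());
  for (int i = 0; i < n; ++i) {
    double P[3] = {origin(i, 0), origin(i, 1), origin(i, 2)};
    double Q[3] = {target(i, 0), target(i, 1), target(i, 2)};
    double D[3] = {Q[0] - P[0], Q[1] - P[1], Q[2] - P[2]};
    double len = std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
    if (len <= 0) { out[i] = 0.0; continue; }
    for (int k = 0; k < 3; ++k) D[k] /= len;
    out[i] = method == 0 ? tungsten_path_analytic(a.data(), P, D, len)
                         : tungsten_path_march(a.data(), P, D, len, step);
  }
  return out;
}

// ------------------------- detector response ------------------------------

struct Detector {
  int n_pix;        // full pixels per side (80)
  double pitch;     // mm
  double f;         // aperture plane -> detector entrance, mm
  int n_lay;        // DOI layers
  double lay_t;     // mm per layer
  double mu_det;    // /mm
  int iu0, iv0;     // pixel window origin (0-based, full-resolution pixels)
  int nu, nv;       // window size in binned super-pixels
  int bin;          // binning factor
};

static Detector as_detector(List det) {
  Detector d;
  d.n_pix = as<int>(det["n_pix"]);
  d.pitch = as<double>(det["pitch"]);
  d.f = as<double>(det["f"]);
  d.n_lay = as<int>(det["n_lay"]);
  d.lay_t = as<double>(det["lay_t"]);
  d.mu_det = as<double>(det["mu_det"]);
  d.iu0 = as<int>(det["iu0"]);
  d.iv0 = as<int>(det["iv0"]);
  d.nu = as<int>(det["nu"]);
  d.nv = as<int>(det["nv"]);
  d.bin = as<int>(det["bin"]);
  return d;
}

static inline double pix_coord(const Detector &d, int i0, int a) {
  return (i0 + (a + 0.5) * d.bin - d.n_pix / 2.0) * d.pitch;
}

struct RespOpts {
  bool penetration;   // model tungsten penetration (else binary open/blocked)
  bool detector_abs;  // model CZT absorption (else perfect detector)
  bool collapse_doi;  // sum DOI layers into one bin
  double floor_val;   // drop entries below this probability
  double mu_obj;      // water attenuation /mm, 0 = off
  double fov_radius;  // mm, for object attenuation chord
};

static RespOpts as_opts(List o) {
  RespOpts r;
  r.penetration = as<bool>(o["penetration"]);
  r.detector_abs = as<bool>(o["detector_abs"]);
  r.collapse_doi = as<bool>(o["collapse_doi"]);
  r.floor_val = as<double>(o["floor"]);
  r.mu_obj = as<double>(o["mu_obj"]);
  r.fov_radius = as<double>(o["fov_radius"]);
  return r;
}

// world -> local of point p for MCE row (center c, basis u,v,w)
static inline void to_local(const double *m, const double *p, double *out) {
  double d0 = p[0] - m[0], d1 = p[1] - m[1], d2 = p[2] - m[2];
  out[0] = d0 * m[3] + d1 * m[4] + d2 * m[5];
  out[1] = d0 * m[6] + d1 * m[7] + d2 * m[8];
  out[2] = d0 * m[9] + d1 * m[10] + d2 * m[11];
}

// chord from point along dir to the FOV sphere boundary (forward direction)
static inline double sphere_exit_chord(const double *p, const double *D,
                                       double R) {
  double b = p[0] * D[0] + p[1] * D[1] + p[2] * D[2];
  double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - R * R;
  double disc = b * b - c;
  if (disc <= 0) return 0.0;
  double s = -b + std::sqrt(disc);
  return s > 0 ? s : 0.0;
}

// Accumulate the response of one voxel through one MCE.
// emit(row0, value): row0 is the 0-based bin index within this MCE.
// Object attenuation (uniform water inside the FOV sphere) is applied as one
// chord per (voxel, MCE) pair along the voxel -> aperture-centre direction;
// the aperture subtends a small angle from any FOV voxel so the per-pixel
// variation of the chord is negligible.
template <typename Emit>
static void voxel_mce_response(const double *mce, const double *ap,
                               const Detector &det, const RespOpts &opt,
                               const double *p_world, Emit emit) {
  double P[3];
  to_local(mce, p_world, P);
  double t_obj = 1.0;
  if (opt.mu_obj > 0) {
    double Dw[3] = {mce[0] - p_world[0], mce[1] - p_world[1],
                    mce[2] - p_world[2]};
    double nrm = std::sqrt(Dw[0] * Dw[0] + Dw[1] * Dw[1] + Dw[2] * Dw[2]);
    for (int k = 0; k < 3; ++k) Dw[k] /= nrm;
    t_obj = std::exp(-opt.mu_obj *
                     sphere_exit_chord(p_world, Dw, opt.fov_radius));
  }
  double area = det.bin * det.pitch * det.bin * det.pitch;
  double mu_w = ap[3];
  int nlay_out = opt.collapse_doi ? 1 : det.n_lay;
  for (int a = 0; a < det.nu; ++a) {
    double tu = pix_coord(det, det.iu0, a);
    for (int b = 0; b < det.nv; ++b) {
      double tv = pix_coord(det, det.iv0, b);
      double D[3] = {tu - P[0], tv - P[1], det.f - P[2]};
      double dist2 = D[0] * D[0] + D[1] * D[1] + D[2] * D[2];
      double dist = std::sqrt(dist2);
      for (int k = 0; k < 3; ++k) D[k] /= dist;
      double cosg = D[2];
      if (cosg <= 1e-6) continue;
      double x = tungsten_path_analytic(ap, P, D, dist);
      double trans;
      if (x <= 0) trans = 1.0;
      else if (!opt.penetration) continue;
      else {
        double mx = mu_w * x;
        if (mx > 60) continue;
        trans = std::exp(-mx);
      }
      double g = area * cosg / dist2 / (4.0 * M_PI) * trans * t_obj;
      if (opt.detector_abs) {
        double c = det.lay_t / cosg;
        double q = std::exp(-det.mu_det * c);
        if (opt.collapse_doi) {
          double val = g * (1.0 - std::pow(q, det.n_lay));
          if (val >= opt.floor_val) emit((a * det.nv + b) * nlay_out, val);
        } else {
          double before = 1.0;
          for (int k = 0; k < det.n_lay; ++k) {
            double val = g * before * (1.0 - q);
            if (val >= opt.floor_val) emit((a * det.nv + b) * nlay_out + k, val);
            before *= q;
          }
        }
      } else {
        if (g >= opt.floor_val) emit((a * det.nv + b) * nlay_out, 0.0 + g);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_point_sensitivity(NumericMatrix points, NumericMatrix mces,
                           NumericMatrix aps, List det_, List opts_) {
  Detector det = as_detector(det_);
  RespOpts opt = as_opts(opts_);
  opt.mu_obj = 0.0;  // sensitivity is defined without object attenuation
  int np = points.nrow(), nm = mces.nrow();
  NumericMatrix per_mce(np, nm);
  NumericVector total(np);
  std::vector<double> mrow(12), arow(AP_NPAR);
  for (int m = 0; m < nm; ++m) {
    for (int c = 0; c < 12; ++c) mrow[c] = mces(m, c);
    for (int c = 0; c < AP_NPAR; ++c) arow[c] = aps(m, c);
    for (int i = 0; i < np; ++i) {
      double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
      double acc = 0.0;
      voxel_mce_response(mrow.data(), arow.data(), det, opt, p,
                         [&](int, double v) { acc += v; });
      per_mce(i, m) = acc;
      total[i] += acc;
    }
    if (m % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["total"] = total, _["per_mce"] = per_mce);
}

// Emits the response columns of the supplied points in compressed sparse
// column form (0-based row indices, column pointers), ready to be wrapped
// as a dgCMatrix without re-sorting.
// [[Rcpp::export]]
List cpp_response_csc(NumericMatrix points, NumericMatrix mces,
                      NumericMatrix aps, List det_, List opts_) {
  Detector det = as_detector(det_);
  RespOpts opt = as_opts(opts_);
  int np = points.nrow(), nm = mces.nrow();
  int nlay_out = opt.collapse_doi ? 1 : det.n_lay;
  int bins_per_mce = det.nu * det.nv * nlay_out;
  std::vector<int> ri;
  std::vector<double> xv;
  IntegerVector colp(np + 1);
  ri.reserve(1 << 20); xv.reserve(1 << 20);
  std::vector<double> mrow(12), arow(AP_NPAR);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    for (int m = 0; m < nm; ++m) {
      for (int c = 0; c < 12; ++c) mrow[c] = mces(m, c);
      for (int c = 0; c < AP_NPAR; ++c) arow[c] = aps(m, c);
      int base = m * bins_per_mce;
      voxel_mce_response(mrow.data(), arow.data(), det, opt, p,
                         [&](int r0, double v) {
                           ri.push_back(base + r0);
                           xv.push_back(v);
                         });
    }
    colp[i + 1] = (double)ri.size();
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(ri), _["p"] = colp, _["x"] = wrap(xv),
                      _["nrow"] = nm * bins_per_mce, _["ncol"] = np);
}

// Streaming forward accumulation: returns the dense bin vector
// sum_i w_i * a(., i) without materialising the response matrix.
// [[Rcpp::export]]
NumericVector cpp_accumulate_bins(NumericMatrix points, NumericVector weights,
                                  NumericMatrix mces, NumericMatrix aps,
                                  List det_, List opts_) {
  Detector det = as_detector(det_);
  RespOpts opt = as_opts(opts_);
  int np = points.nrow(), nm = mces.nrow();
  int nlay_out = opt.collapse_doi ? 1 : det.n_lay;
  int bins_per_mce = det.nu * det.nv * nlay_out;
  NumericVector out(nm * bins_per_mce);
  std::vector<double> mrow(12), arow(AP_NPAR);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double w = weights[i];
    if (w == 0) continue;
    for (int m = 0; m < nm; ++m) {
      for (int c = 0; c < 12; ++c) mrow[c] = mces(m, c);
      for (int c = 0; c < AP_NPAR; ++c) arow[c] = aps(m, c);
      int base = m * bins_per_mce;
      voxel_mce_response(mrow.data(), arow.data(), det, opt, p,
                         [&](int r0, double v) { out[base + r0] += w * v; });
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ------------------------- aperture SNR -----------------------------------

// Eq.-style ray classification for one MCE under a set of source points:
// signal rays have zero tungsten path; noise rays are weighted exp(-mu x).
// [[Rcpp::export]]
List cpp_aperture_snr(NumericMatrix points, NumericVector mce,
                      NumericVector ap, List det_) {
  Detector det = as_detector(det_);
  int np = points.nrow();
  std::vector<double> mrow(mce.begin(), mce.end());
  std::vector<double> arow(ap.begin(), ap.end());
  double mu_w = arow[3];
  double tau = std::exp(-mu_w * (arow[1] + arow[2]));  // full-slab floor
  double n_signal = 0.0, noise_sum = 0.0;
  double n_noise = 0.0, n_blocked = 0.0;
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double P[3];
    to_local(mrow.data(), p, P);
    for (int a = 0; a < det.nu; ++a) {
      double tu = pix_coord(det, det.iu0, a);
      for (int b = 0; b < det.nv; ++b) {
        double tv = pix_coord(det, det.iv0, b);
        double D[3] = {tu - P[0], tv - P[1], det.f - P[2]};
        double len =
            std::sqrt(D[0] * D[0] + D[1] * D[1] + D[2] * D[2]);
        for (int k = 0; k < 3; ++k) D[k] /= len;
        double x = tungsten_path_analytic(arow.data(), P, D, len);
        if (x <= 1e-12) {
          n_signal += 1.0;
        } else {
          double t = std::exp(-mu_w * x);
          noise_sum += t;
          if (t > tau) n_noise += 1.0; else n_blocked += 1.0;
        }
      }
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_signal"] = n_signal, _["noise_sum"] = noise_sum,
                      _["n_noise"] = n_noise, _["n_blocked"] = n_blocked);
}

// ------------------------- point projection rendering ----------------------

// [[Rcpp::export]]
NumericMatrix cpp_render_point_projection(NumericVector point,
                                          NumericVector mce, NumericVector ap,
                                          List det_, int supersample,
                                          List opts_) {
  Detector det = as_detector(det_);
  RespOpts opt = as_opts(opts_);
  std::vector<double> mrow(mce.begin(), mce.end());
  std::vector<double> arow(ap.begin(), ap.end());
  double p[3] = {point[0], point[1], point[2]};
  double P[3];
  to_local(mrow.data(), p, P);
  NumericMatrix img(det.nu, det.nv);
  double mu_w = arow[3];
  double sub = det.bin * det.pitch / supersample;
  double subarea = sub * sub;
  for (int a = 0; a < det.nu; ++a) {
    double u0 = pix_coord(det, det.iu0, a) - det.bin * det.pitch / 2.0;
    for (int b = 0; b < det.nv; ++b) {
      double v0 = pix_coord(det, det.iv0, b) - det.bin * det.pitch / 2.0;
      double acc = 0.0;
      for (int si = 0; si < supersample; ++si) {
        double tu = u0 + (si + 0.5) * sub;
        for (int sj = 0; sj < supersample; ++sj) {
          double tv = v0 + (sj + 0.5) * sub;
          double D[3] = {tu - P[0], tv - P[1], det.f - P[2]};
          double dist2 = D[0] * D[0] + D[1] * D[1] + D[2] * D[2];
          double dist = std::sqrt(dist2);
          for (int k = 0; k < 3; ++k) D[k] /= dist;
          double cosg = D[2];
          if (cosg <= 1e-6) continue;
          double x = tungsten_path_analytic(arow.data(), P, D, dist);
          double trans = x <= 0 ? 1.0
                                : (opt.penetration && mu_w * x < 60
                                       ? std::exp(-mu_w * x)
                                       : 0.0);
          if (trans == 0) continue;
          double g = subarea * cosg / dist2 / (4.0 * M_PI) * trans;
          if (opt.detector_abs)
            g *= 1.0 - std::exp(-det.mu_det * det.n_lay * det.lay_t / cosg);
          acc += g;
        }
      }
      img(a, b) = acc;
    }
  }
  return img;
}

// ------------------------- Monte-Carlo cross-check -------------------------

// Independent estimate of the single-MCE voxel response by uniform area
// sampling of the detector entrance face (quadrature route is pixel-centre
// sums; this route integrates the same integrand by Monte Carlo).
// [[Rcpp::export]]
List cpp_mc_sensitivity(NumericVector point, NumericVector mce,
                        NumericVector ap, List det_, int n_samples,
                        List opts_) {
  Detector det = as_detector(det_);
  RespOpts opt = as_opts(opts_);
  std::vector<double> mrow(mce.begin(), mce.end());
  std::vector<double> arow(ap.begin(), ap.end());
  double p[3] = {point[0], point[1], point[2]};
  double P[3];
  to_local(mrow.data(), p, P);
  double half = det.n_pix * det.pitch / 2.0;
  double area = (2 * half) * (2 * half);
  double mu_w = arow[3];
  double sum = 0.0, sum2 = 0.0;
  RNGScope scope;
  for (int i = 0; i < n_samples; ++i) {
    double tu = (unif_rand() * 2.0 - 1.0) * half;
    double tv = (unif_rand() * 2.0 - 1.0) * half;
    double D[3] = {tu - P[0], tv - P[1], det.f - P[2]};
    double dist2 = D[0] * D[0] + D[1] * D[1] + D[2] * D[2];
    double dist = std::sqrt(dist2);
    for (int k = 0; k < 3; ++k) D[k] /= dist;
    double cosg = D[2];
    double val = 0.0;
    if (cosg > 1e-6) {
      double x = tungsten_path_analytic(arow.data(), P, D, dist);
      double trans = x <= 0 ? 1.0
                            : (opt.penetration && mu_w * x < 60
                                   ? std::exp(-mu_w * x)
                                   : 0.0);
      if (trans > 0) {
        val = cosg / dist2 / (4.0 * M_PI) * trans;
        if (opt.detector_abs)
          val *= 1.0 - std::exp(-det.mu_det * det.n_lay * det.lay_t / cosg);
      }
    }
    sum += val;
    sum2 += val * val;
  }
  double mean = sum / n_samples;
  double var = (sum2 / n_samples - mean * mean) / n_samples;
  return List::create(_["estimate"] = mean * area,
                      _["se"] = std::sqrt(std::max(var, 0.0)) * area);
}
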