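// Analog photon transport for an encapsulated HDR 60Co line source in
// cylindrical / spherical phantoms, with track-length ring tallies and
// next-event point detectors.  Geometry is the fixed nested source model
// (core / air gap / steel capsule / cable) centred in a single phantom.
//
// All lengths cm, energies MeV.  Cross-section tables arrive from R as
// fine uniform-in-log(E) grids (cm^-1 per process); interpolation is
// log-log.  Randomness comes from R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double MEC2 = 0.51099895;        // electron rest energy, MeV
static const double RE2 = 7.94079e-26;        // classical electron radius^2, cm^2
static const double INF_T = 1e30;
static const double EPSB = 1e-11;             // boundary tolerance, cm
static const double NUDGE = 1e-9;             // push across surfaces, cm

// fixed source dimensions (cm)
static const double CORE_R = 0.025, CORE_HL = 0.175;
static const double GAP_R = 0.035, GAP_HL = 0.185;
static const double CAP_R = 0.050, CAP_HL = 0.200;
static const double CABLE_Z0 = -0.400, CABLE_Z1 = -0.200;

// ------------------------------------------------------------------ tables --
struct Fine {
  const double* col[5];   // pe, incoherent, coherent, pair, total-enabled
  double logE0, dlog;
  int n;
  bool vacuum;
};

static Fine make_fine(SEXP m) {
  Fine f;
  if (Rf_isNull(m)) { f.vacuum = true; f.n = 0; return f; }
  NumericMatrix mm(m);
  f.vacuum = false;
  f.n = mm.nrow();
  f.logE0 = as<double>(mm.attr("logE0"));
  f.dlog = as<double>(mm.attr("dlog"));
  for (int j = 0; j < 5; ++j) f.col[j] = &mm(0, j);
  return f;
}

static inline double fine_at(const Fine& f, int j, double E) {
  if (f.vacuum) return 0.0;
  double u = (std::log(E) - f.logE0) / f.dlog;
  if (u < 0) u = 0;
  if (u > f.n - 1.000001) u = f.n - 1.000001;
  int i = (int)u;
  double w = u - i;
  double a = f.col[j][i], b = f.col[j][i + 1];
  if (a <= 0.0 || b <= 0.0) {
    double v = a + w * (b - a);
    return v > 0 ? v : 0.0;
  }
  return std::exp((1.0 - w) * std::log(a) + w * std::log(b));
}

struct Fine1 {                 // single-column fine grid (mu_en/rho, cm^2/g)
  const double* v;
  double logE0, dlog;
  int n;
};

static Fine1 make_fine1(NumericVector x) {
  Fine1 f;
  f.v = &x[0];
  f.n = x.size();
  f.logE0 = as<double>(x.attr("logE0"));
  f.dlog = as<double>(x.attr("dlog"));
  return f;
}

static inline double fine1_at(const Fine1& f, double E) {
  double u = (std::log(E) - f.logE0) / f.dlog;
  if (u < 0) u = 0;
  if (u > f.n - 1.000001) u = f.n - 1.000001;
  int i = (int)u;
  double w = u - i;
  return std::exp((1.0 - w) * std::log(f.v[i]) + w * std::log(f.v[i + 1]));
}

// ---------------------------------------------------------------- geometry --
struct Geom {
  int shape;        // 0 cylinder, 1 sphere
  double R, HH;     // phantom radius, half-height (cylinder only)
};

static inline int locate_pt(double x, double y, double z, const Geom& g) {
  double r2 = x * x + y * y;
  if (r2 <= CORE_R * CORE_R && std::fabs(z) <= CORE_HL) return 0;
  if (r2 <= GAP_R * GAP_R && std::fabs(z) <= GAP_HL) return 1;
  if (r2 <= CAP_R * CAP_R && std::fabs(z) <= CAP_HL) return 2;
  if (r2 <= CAP_R * CAP_R && z >= CABLE_Z0 && z <= CABLE_Z1) return 3;
  if (g.shape == 0) {
    if (r2 < g.R * g.R && std::fabs(z) < g.HH) return 4;
  } else {
    if (r2 + z * z < g.R * g.R) return 4;
  }
  return 5;
}

static inline void cyl_roots(double px, double py, double dx, double dy,
                             double R, double& t1, double& t2) {
  double a = dx * dx + dy * dy;
  if (a < 1e-20) { t1 = t2 = INF_T; return; }
  double b = 2.0 * (px * dx + py * dy), c = px * px + py * py - R * R;
  double disc = b * b - 4.0 * a * c;
  if (disc < 0) { t1 = t2 = INF_T; return; }
  double sq = std::sqrt(disc);
  t1 = (-b - sq) / (2.0 * a);
  t2 = (-b + sq) / (2.0 * a);
}

// first t > EPSB at which a ray from phantom space enters the source
// structure (finite cylinder r < CAP_R, CABLE_Z0 <= z <= CAP_HL)
static inline double structure_entry(const double* p, const double* d) {
  double tc1, tc2;
  double a = d[0] * d[0] + d[1] * d[1];
  if (a < 1e-20) {
    double r2 = p[0] * p[0] + p[1] * p[1];
    if (r2 >= CAP_R * CAP_R) return INF_T;
    tc1 = -INF_T; tc2 = INF_T;
  } else {
    cyl_roots(p[0], p[1], d[0], d[1], CAP_R, tc1, tc2);
    if (tc1 >= INF_T) return INF_T;
  }
  double tz1, tz2;
  if (std::fabs(d[2]) < 1e-20) {
    if (p[2] < CABLE_Z0 || p[2] > CAP_HL) return INF_T;
    tz1 = -INF_T; tz2 = INF_T;
  } else {
    tz1 = (CABLE_Z0 - p[2]) / d[2];
    tz2 = (CAP_HL - p[2]) / d[2];
    if (tz1 > tz2) std::swap(tz1, tz2);
  }
  double lo = std::max(tc1, tz1), hi = std::min(tc2, tz2);
  if (lo > EPSB && lo < hi) return lo;
  return INF_T;
}

// distance to next region boundary from inside `region`
static double next_boundary(const double* p, const double* d, int region,
                            const Geom& g) {
  double best = INF_T, t1, t2;
  if (region <= 3) {
    const double rads[3] = { CORE_R, GAP_R, CAP_R };
    for (int k = 0; k < 3; ++k) {
      cyl_roots(p[0], p[1], d[0], d[1], rads[k], t1, t2);
      if (t1 > EPSB && t1 < best) best = t1;
      if (t2 > EPSB && t2 < best) best = t2;
    }
    const double zs[7] = { -CORE_HL, CORE_HL, -GAP_HL, GAP_HL,
                           -CAP_HL, CAP_HL, CABLE_Z0 };
    if (std::fabs(d[2]) > 1e-20) {
      for (int k = 0; k < 7; ++k) {
        double t = (zs[k] - p[2]) / d[2];
        if (t > EPSB && t < best) best = t;
      }
    }
  } else if (region == 4) {
    double te = structure_entry(p, d);
    if (te < best) best = te;
  } else {
    return INF_T;
  }
  // phantom outer surface
  if (g.shape == 0) {
    cyl_roots(p[0], p[1], d[0], d[1], g.R, t1, t2);
    if (t1 > EPSB && t1 < best) best = t1;
    if (t2 > EPSB && t2 < best) best = t2;
    if (std::fabs(d[2]) > 1e-20) {
      double t = (g.HH - p[2]) / d[2];
      if (t > EPSB && t < best) best = t;
      t = (-g.HH - p[2]) / d[2];
      if (t > EPSB && t < best) best = t;
    }
  } else {
    double b = 2.0 * (p[0] * d[0] + p[1] * d[1] + p[2] * d[2]);
    double c = p[0] * p[0] + p[1] * p[1] + p[2] * p[2] - g.R * g.R;
    double disc = b * b - 4.0 * c;
    if (disc >= 0) {
      double sq = std::sqrt(disc);
      t1 = (-b - sq) / 2.0; t2 = (-b + sq) / 2.0;
      if (t1 > EPSB && t1 < best) best = t1;
      if (t2 > EPSB && t2 < best) best = t2;
    }
  }
  return best;
}

// ------------------------------------------------------------------ physics --
// [[Rcpp::export]]
double cpp_kn_sigma_total(double E) {
  double a = E / MEC2;
  return 2.0 * M_PI * RE2 *
    ((1.0 + a) / (a * a) * (2.0 * (1.0 + a) / (1.0 + 2.0 * a) -
                            std::log(1.0 + 2.0 * a) / a) +
     std::log(1.0 + 2.0 * a) / (2.0 * a) -
     (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a)));
}

// [[Rcpp::export]]
NumericVector cpp_kn_dsigma_domega(double E, NumericVector cth) {
  double a = E / MEC2;
  int n = cth.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double eps = 1.0 / (1.0 + a * (1.0 - cth[i]));
    double s2 = 1.0 - cth[i] * cth[i];
    out[i] = 0.5 * RE2 * eps * eps * (eps + 1.0 / eps - s2);
  }
  return out;
}

static inline double sample_kn(double E, double& cth) {
  double a = E / MEC2;
  double e0 = 1.0 / (1.0 + 2.0 * a), e0sq = e0 * e0;
  double a1 = -std::log(e0), a2 = 0.5 * (1.0 - e0sq);
  double eps, t;
  do {
    if (unif_rand() * (a1 + a2) < a1) {
      eps = std::exp(-a1 * unif_rand());
    } else {
      eps = std::sqrt(e0sq + (1.0 - e0sq) * unif_rand());
    }
    t = (1.0 - eps) / (a * eps);
  } while (unif_rand() > 1.0 - eps * t * (2.0 - t) / (1.0 + eps * eps));
  cth = 1.0 - t;
  return eps * E;
}

static inline double sample_thomson_cth() {
  // pdf proportional to 1 + cos^2(theta)
  double c;
  do { c = 2.0 * unif_rand() - 1.0; } while (unif_rand() * 2.0 > 1.0 + c * c);
  return c;
}

// rotate unit vector u by polar angle with cosine cth (uniform azimuth)
static inline void rotate_dir(double* u, double cth) {
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double phi = 2.0 * M_PI * unif_rand();
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  double s2 = ux * ux + uy * uy;
  if (s2 > 1e-20) {
    double s = std::sqrt(s2);
    u[0] = cth * ux + sth * (uz * ux * cphi - uy * sphi) / s;
    u[1] = cth * uy + sth * (uz * uy * cphi + ux * sphi) / s;
    u[2] = cth * uz - sth * s * cphi;
  } else {
    u[0] = sth * cphi;
    u[1] = sth * sphi;
    u[2] = (uz > 0 ? cth : -cth);
  }
  double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

static inline void iso_dir(double* u) {
  u[2] = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - u[2] * u[2]));
  u[0] = s * std::cos(phi);
  u[1] = s * std::sin(phi);
}

// ------------------------------------------------------------------- tally --
struct Tally {
  std::vector<double> r_edges, z_edges;   // r_edges[0] == 0
  std::vector<int> cellmap;               // (nr) x (nz) bins -> cell or -1
  int nr, nz, ncell;
  std::vector<double> inv_vol;
  std::vector<double> k_sum, k_ssq, k_cur, f_sum, f_ssq, f_cur;
  std::vector<int> last;
  double rmax, zmin, zmax;
  std::vector<double> ts;                 // scratch crossing times

  void init(List spec) {
    r_edges = as<std::vector<double> >(spec["r_edges"]);
    z_edges = as<std::vector<double> >(spec["z_edges"]);
    IntegerMatrix cm = spec["cellmap"];
    nr = cm.nrow(); nz = cm.ncol();
    cellmap.assign(cm.begin(), cm.end());
    NumericVector v = spec["volumes"];
    ncell = v.size();
    inv_vol.resize(ncell);
    for (int i = 0; i < ncell; ++i) inv_vol[i] = 1.0 / v[i];
    k_sum.assign(ncell, 0); k_ssq.assign(ncell, 0); k_cur.assign(ncell, 0);
    f_sum.assign(ncell, 0); f_ssq.assign(ncell, 0); f_cur.assign(ncell, 0);
    last.assign(ncell, -1);
    rmax = r_edges.back();
    zmin = z_edges.front(); zmax = z_edges.back();
    ts.reserve(512);
  }

  inline void add(int cell, double flu, double ker, int hist) {
    if (last[cell] != hist) {
      k_sum[cell] += k_cur[cell]; k_ssq[cell] += k_cur[cell] * k_cur[cell];
      f_sum[cell] += f_cur[cell]; f_ssq[cell] += f_cur[cell] * f_cur[cell];
      k_cur[cell] = 0; f_cur[cell] = 0;
      last[cell] = hist;
    }
    f_cur[cell] += flu;
    k_cur[cell] += ker;
  }

  void flush() {
    for (int c = 0; c < ncell; ++c) {
      k_sum[c] += k_cur[c]; k_ssq[c] += k_cur[c] * k_cur[c]; k_cur[c] = 0;
      f_sum[c] += f_cur[c]; f_ssq[c] += f_cur[c] * f_cur[c]; f_cur[c] = 0;
      last[c] = -2;
    }
  }

  // score one straight flight segment (track-length estimator)
  void score(const double* p, const double* d, double len, double E,
             double w, int hist, const Fine1& muen) {
    if (len <= 0) return;
    double a = d[0] * d[0] + d[1] * d[1];
    double b = 2.0 * (p[0] * d[0] + p[1] * d[1]);
    double c = p[0] * p[0] + p[1] * p[1];
    // clip to ROI cylinder r < rmax
    double t0 = 0.0, t1 = len;
    if (a > 1e-20) {
      double disc = b * b - 4.0 * a * (c - rmax * rmax);
      if (disc <= 0) return;                       // never inside ROI radius
      double sq = std::sqrt(disc);
      double ta = (-b - sq) / (2 * a), tb = (-b + sq) / (2 * a);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    } else if (c >= rmax * rmax) return;
    // clip to ROI z slab
    if (std::fabs(d[2]) > 1e-20) {
      double ta = (zmin - p[2]) / d[2], tb = (zmax - p[2]) / d[2];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    } else if (p[2] <= zmin || p[2] >= zmax) return;
    if (t0 >= t1) return;

    ts.clear();
    ts.push_back(t0); ts.push_back(t1);
    // z-plane crossings
    if (std::fabs(d[2]) > 1e-20) {
      for (size_t k = 1; k + 1 < z_edges.size(); ++k) {
        double t = (z_edges[k] - p[2]) / d[2];
        if (t > t0 && t < t1) ts.push_back(t);
      }
    }
    // radial crossings: restrict to edge radii within the segment's r range
    double r0 = std::sqrt(std::max(0.0, a * t0 * t0 + b * t0 + c));
    double r1 = std::sqrt(std::max(0.0, a * t1 * t1 + b * t1 + c));
    double rlo = std::min(r0, r1), rhi = std::max(r0, r1);
    if (a > 1e-20) {
      double tap = -b / (2 * a);
      if (tap > t0 && tap < t1) {
        double rm2 = c - b * b / (4 * a);
        rlo = std::min(rlo, std::sqrt(std::max(0.0, rm2)));
      }
      size_t klo = std::lower_bound(r_edges.begin(), r_edges.end(), rlo) -
        r_edges.begin();
      size_t khi = std::upper_bound(r_edges.begin(), r_edges.end(), rhi) -
        r_edges.begin();
      for (size_t k = (klo == 0 ? 1 : klo); k < khi && k < r_edges.size(); ++k) {
        double tt1, tt2;
        cyl_roots(p[0], p[1], d[0], d[1], r_edges[k], tt1, tt2);
        if (tt1 > t0 && tt1 < t1) ts.push_back(tt1);
        if (tt2 > t0 && tt2 < t1) ts.push_back(tt2);
      }
    }
    std::sort(ts.begin(), ts.end());

    double kfac = E * fine1_at(muen, E);
    for (size_t k = 0; k + 1 < ts.size(); ++k) {
      double ta = ts[k], tb = ts[k + 1];
      double dl = tb - ta;
      if (dl <= 1e-14) continue;
      double tm = 0.5 * (ta + tb);
      double rm = std::sqrt(std::max(0.0, a * tm * tm + b * tm + c));
      double zm = p[2] + tm * d[2];
      if (rm >= rmax || zm <= zmin || zm >= zmax) continue;
      int ir = std::upper_bound(r_edges.begin(), r_edges.end(), rm) -
        r_edges.begin() - 1;
      int iz = std::upper_bound(z_edges.begin(), z_edges.end(), zm) -
        z_edges.begin() - 1;
      if (ir < 0 || ir >= nr || iz < 0 || iz >= nz) continue;
      int cell = cellmap[ir + nr * iz];
      if (cell < 0) continue;
      double wl = w * dl * inv_vol[cell];
      add(cell, wl, wl * kfac, hist);
    }
  }
};

// spectrum tally: a few ring cells, energy-binned track-length fluence
struct SpecTally {
  std::vector<double> r1, r2, zl, zh, inv_vol;
  std::vector<double> edges;
  int ncell, nbin;
  std::vector<double> flu;    // ncell x nbin

  void init(List spec) {
    NumericMatrix cm = spec["cells"];     // r1, r2, z1, z2, volume
    ncell = cm.nrow();
    for (int i = 0; i < ncell; ++i) {
      r1.push_back(cm(i, 0)); r2.push_back(cm(i, 1));
      zl.push_back(cm(i, 2)); zh.push_back(cm(i, 3));
      inv_vol.push_back(1.0 / cm(i, 4));
    }
    edges = as<std::vector<double> >(spec["edges"]);
    nbin = edges.size() - 1;
    flu.assign(ncell * nbin, 0.0);
  }

  void score(const double* p, const double* d, double len, double E, double w) {
    int ib = std::upper_bound(edges.begin(), edges.end(), E) - edges.begin() - 1;
    if (ib < 0 || ib >= nbin) return;
    double a = d[0] * d[0] + d[1] * d[1];
    double b = 2.0 * (p[0] * d[0] + p[1] * d[1]);
    double c = p[0] * p[0] + p[1] * p[1];
    for (int i = 0; i < ncell; ++i) {
      // z window
      double t0 = 0, t1 = len;
      if (std::fabs(d[2]) > 1e-20) {
        double ta = (zl[i] - p[2]) / d[2], tb = (zh[i] - p[2]) / d[2];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      } else if (p[2] <= zl[i] || p[2] >= zh[i]) continue;
      if (t0 >= t1) continue;
      // inside outer radius
      double o1 = t0, o2 = t1;
      if (a > 1e-20) {
        double tt1, tt2;
        cyl_roots(p[0], p[1], d[0], d[1], r2[i], tt1, tt2);
        if (tt1 >= INF_T) continue;
        if (tt1 > o1) o1 = tt1;
        if (tt2 < o2) o2 = tt2;
      } else if (c >= r2[i] * r2[i]) continue;
      if (o1 >= o2) continue;
      // subtract time inside inner radius
      double L = o2 - o1;
      if (r1[i] > 0 && a > 1e-20) {
        double tt1, tt2;
        cyl_roots(p[0], p[1], d[0], d[1], r1[i], tt1, tt2);
        if (tt1 < INF_T) {
          double s1 = std::max(o1, tt1), s2 = std::min(o2, tt2);
          if (s2 > s1) L -= (s2 - s1);
        }
      } else if (r1[i] > 0 && c < r1[i] * r1[i]) {
        continue;    // axial ray inside the hole
      }
      if (L > 0) flu[i + ncell * ib] += w * L * inv_vol[i];
    }
  }
};

// --------------------------------------------------------------- detectors --
struct Detectors {
  std::vector<double> x, y, z;
  int n;
  std::vector<double> f_sum, k_sum, k_ssq, k_cur;
  std::vector<int> last;

  void init(NumericMatrix pos) {
    n = pos.nrow();
    for (int i = 0; i < n; ++i) {
      x.push_back(pos(i, 0)); y.push_back(pos(i, 1)); z.push_back(pos(i, 2));
    }
    f_sum.assign(n, 0); k_sum.assign(n, 0); k_ssq.assign(n, 0);
    k_cur.assign(n, 0); last.assign(n, -1);
  }

  inline void add(int i, double flu, double ker, int hist) {
    if (last[i] != hist) {
      k_sum[i] += k_cur[i]; k_ssq[i] += k_cur[i] * k_cur[i];
      k_cur[i] = 0; last[i] = hist;
    }
    f_sum[i] += flu;
    k_cur[i] += ker;
  }

  void flush() {
    for (int i = 0; i < n; ++i) {
      k_sum[i] += k_cur[i]; k_ssq[i] += k_cur[i] * k_cur[i]; k_cur[i] = 0;
    }
  }
};

// optical depth along the straight ray p -> q at energy E
static double optical_depth(const double* p, const double* q, double E,
                            const Geom& g, const std::vector<Fine>& mats) {
  double d[3] = { q[0] - p[0], q[1] - p[1], q[2] - p[2] };
  double dist = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (dist <= 0) return 0.0;
  d[0] /= dist; d[1] /= dist; d[2] /= dist;
  double cur[3] = { p[0], p[1], p[2] };
  double tau = 0.0, travelled = 0.0;
  int steps = 0;
  while (travelled < dist - EPSB && steps++ < 1000) {
    int reg = locate_pt(cur[0], cur[1], cur[2], g);
    if (reg == 5) break;
    double tb = next_boundary(cur, d, reg, g);
    double seg = std::min(tb, dist - travelled);
    if (!mats[reg].vacuum) tau += fine_at(mats[reg], 4, E) * seg;
    if (seg >= dist - travelled - EPSB) break;
    travelled += seg + NUDGE;
    cur[0] = p[0] + travelled * d[0];
    cur[1] = p[1] + travelled * d[1];
    cur[2] = p[2] + travelled * d[2];
  }
  return tau;
}

// ------------------------------------------------------------ exported API --

// [[Rcpp::export]]
IntegerVector cpp_locate(NumericMatrix pts, List geom) {
  Geom g = { as<int>(geom["shape"]), as<double>(geom["radius"]),
             as<double>(geom["half_height"]) };
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = locate_pt(pts(i, 0), pts(i, 1), pts(i, 2), g);
  return out;
}

// [[Rcpp::export]]
List cpp_next_boundary(NumericVector p, NumericVector d, List geom) {
  Geom g = { as<int>(geom["shape"]), as<double>(geom["radius"]),
             as<double>(geom["half_height"]) };
  double pp[3] = { p[0], p[1], p[2] }, dd[3] = { d[0], d[1], d[2] };
  int reg = locate_pt(pp[0], pp[1], pp[2], g);
  double t = next_boundary(pp, dd, reg, g);
  int nxt = NA_INTEGER;
  if (t < INF_T) {
    double s = t + NUDGE;
    nxt = locate_pt(pp[0] + s * dd[0], pp[1] + s * dd[1], pp[2] + s * dd[2], g);
  }
  return List::create(_["distance"] = t < INF_T ? t : R_PosInf,
                      _["region"] = reg, _["next_region"] = nxt);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_source(int n) {
  RNGScope scope;
  NumericMatrix out(n, 7);   // x y z ux uy uz E
  for (int i = 0; i < n; ++i) {
    double r = CORE_R * std::sqrt(unif_rand());
    double phi = 2.0 * M_PI * unif_rand();
    out(i, 0) = r * std::cos(phi);
    out(i, 1) = r * std::sin(phi);
    out(i, 2) = CORE_HL * (2.0 * unif_rand() - 1.0);
    double u[3];
    iso_dir(u);
    out(i, 3) = u[0]; out(i, 4) = u[1]; out(i, 5) = u[2];
    out(i, 6) = unif_rand() < 0.5 ? 1.17 : 1.33;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_compton_sample(double E, int n) {
  RNGScope scope;
  NumericMatrix out(n, 2);   // E', cos(theta)
  for (int i = 0; i < n; ++i) {
    double cth;
    out(i, 0) = sample_kn(E, cth);
    out(i, 1) = cth;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_optical_depth(NumericVector p, NumericVector q, double E,
                         List geom, List mats) {
  Geom g = { as<int>(geom["shape"]), as<double>(geom["radius"]),
             as<double>(geom["half_height"]) };
  std::vector<Fine> fm;
  for (int i = 0; i < 5; ++i) fm.push_back(make_fine(mats[i]));
  double pp[3] = { p[0], p[1], p[2] }, qq[3] = { q[0], q[1], q[2] };
  return optical_depth(pp, qq, E, g, fm);
}

// [[Rcpp::export]]
List cpp_score_segments(List tally_spec, NumericMatrix segs,
                        NumericVector muen) {
  // segs columns: x y z ux uy uz length energy weight history
  Tally T;
  T.init(tally_spec);
  Fine1 mu = make_fine1(muen);
  int n = segs.nrow();
  for (int i = 0; i < n; ++i) {
    double p[3] = { segs(i, 0), segs(i, 1), segs(i, 2) };
    double d[3] = { segs(i, 3), segs(i, 4), segs(i, 5) };
    T.score(p, d, segs(i, 6), segs(i, 7), segs(i, 8), (int)segs(i, 9), mu);
  }
  T.flush();
  return List::create(_["kerma_sum"] = wrap(T.k_sum),
                      _["kerma_ssq"] = wrap(T.k_ssq),
                      _["fluence_sum"] = wrap(T.f_sum),
                      _["fluence_ssq"] = wrap(T.f_ssq));
}

// full analog transport run
// [[Rcpp::export]]
List cpp_run(int n_hist, List geom, List mats, bool coherent_on, bool pair_on,
             double cutoff, Nullable<List> tally_spec,
             Nullable<NumericMatrix> det_pos, Nullable<List> spectrum_spec,
             NumericVector muen_score, NumericVector muen_air_fine,
             int max_steps) {
  RNGScope scope;
  Geom g = { as<int>(geom["shape"]), as<double>(geom["radius"]),
             as<double>(geom["half_height"]) };
  std::vector<Fine> fm;
  for (int i = 0; i < 5; ++i) fm.push_back(make_fine(mats[i]));
  Fine1 mu_sc = make_fine1(muen_score);
  Fine1 mu_air = make_fine1(muen_air_fine);

  bool have_tally = tally_spec.isNotNull();
  Tally T;
  if (have_tally) T.init(tally_spec.get());

  bool have_det = det_pos.isNotNull();
  Detectors D;
  if (have_det) D.init(det_pos.get());

  bool have_spec = spectrum_spec.isNotNull();
  SpecTally S;
  if (have_spec) S.init(spectrum_spec.get());

  long long n_escape = 0, n_absorbed = 0, n_cutoff = 0;
  double stack[8][7];   // pair-production secondaries

  for (int h = 0; h < n_hist; ++h) {
    if ((h & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    // primary photon
    double pos[3], dir[3], E;
    {
      double r = CORE_R * std::sqrt(unif_rand());
      double phi = 2.0 * M_PI * unif_rand();
      pos[0] = r * std::cos(phi);
      pos[1] = r * std::sin(phi);
      pos[2] = CORE_HL * (2.0 * unif_rand() - 1.0);
      iso_dir(dir);
      E = unif_rand() < 0.5 ? 1.17 : 1.33;
    }
    int nstack = 0;

    // next-event contribution of the (isotropic) emission
    if (have_det) {
      for (int i = 0; i < D.n; ++i) {
        double q[3] = { D.x[i], D.y[i], D.z[i] };
        double dx = q[0] - pos[0], dy = q[1] - pos[1], dz = q[2] - pos[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        double tau = optical_depth(pos, q, E, g, fm);
        double f = std::exp(-tau) / (4.0 * M_PI * d2);
        D.add(i, f, f * E * fine1_at(mu_air, E), h);
      }
    }

    bool have_photon = true;
    int steps = 0;
    while (have_photon) {
      if (++steps > max_steps) break;
      int reg = locate_pt(pos[0], pos[1], pos[2], g);
      if (reg == 5) {
        ++n_escape;
        goto next_photon;
      }
      {
        const Fine& mat = fm[reg];
        double mu_tot = mat.vacuum ? 0.0 : fine_at(mat, 4, E);
        double tb = next_boundary(pos, dir, reg, g);
        double s = (mu_tot > 0.0) ? -std::log(unif_rand()) / mu_tot : INF_T;
        double seg = std::min(s, tb);
        if (seg >= INF_T) { ++n_escape; goto next_photon; }
        if (have_tally) T.score(pos, dir, seg, E, 1.0, h, mu_sc);
        if (have_spec) S.score(pos, dir, seg, E, 1.0);
        if (s < tb) {
          // collision
          pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
          double m_pe = fine_at(mat, 0, E), m_in = fine_at(mat, 1, E);
          double m_co = coherent_on ? fine_at(mat, 2, E) : 0.0;
          double m_pr = pair_on ? fine_at(mat, 3, E) : 0.0;
          double xi = unif_rand() * (m_pe + m_in + m_co + m_pr);
          if (xi < m_pe) {
            ++n_absorbed;
            goto next_photon;
          } else if (xi < m_pe + m_in) {
            // next-event estimate before sampling the real scatter
            if (have_det) {
              double sig = cpp_kn_sigma_total(E);
              double a = E / MEC2;
              for (int i = 0; i < D.n; ++i) {
                double q[3] = { D.x[i], D.y[i], D.z[i] };
                double dx = q[0] - pos[0], dy = q[1] - pos[1],
                  dz = q[2] - pos[2];
                double d2 = dx * dx + dy * dy + dz * dz;
                double dd = std::sqrt(d2);
                double cth = (dx * dir[0] + dy * dir[1] + dz * dir[2]) / dd;
                double eps = 1.0 / (1.0 + a * (1.0 - cth));
                double Ed = eps * E;
                if (Ed < cutoff) continue;
                double dcs = 0.5 * RE2 * eps * eps *
                  (eps + 1.0 / eps - (1.0 - cth * cth));
                double tau = optical_depth(pos, q, Ed, g, fm);
                double f = (dcs / sig) * std::exp(-tau) / d2;
                D.add(i, f, f * Ed * fine1_at(mu_air, Ed), h);
              }
            }
            double cth;
            E = sample_kn(E, cth);
            rotate_dir(dir, cth);
            if (E < cutoff) { ++n_cutoff; goto next_photon; }
          } else if (xi < m_pe + m_in + m_co) {
            if (have_det) {
              for (int i = 0; i < D.n; ++i) {
                double q[3] = { D.x[i], D.y[i], D.z[i] };
                double dx = q[0] - pos[0], dy = q[1] - pos[1],
                  dz = q[2] - pos[2];
                double d2 = dx * dx + dy * dy + dz * dz;
                double dd = std::sqrt(d2);
                double cth = (dx * dir[0] + dy * dir[1] + dz * dir[2]) / dd;
                double pd = 3.0 / (16.0 * M_PI) * (1.0 + cth * cth);
                double tau = optical_depth(pos, q, E, g, fm);
                double f = pd * std::exp(-tau) / d2;
                D.add(i, f, f * E * fine1_at(mu_air, E), h);
              }
            }
            rotate_dir(dir, sample_thomson_cth());
          } else {
            // pair production: two back-to-back 511 keV annihilation photons
            if (have_det) {
              for (int i = 0; i < D.n; ++i) {
                double q[3] = { D.x[i], D.y[i], D.z[i] };
                double dx = q[0] - pos[0], dy = q[1] - pos[1],
                  dz = q[2] - pos[2];
                double d2 = dx * dx + dy * dy + dz * dz;
                double tau = optical_depth(pos, q, MEC2, g, fm);
                double f = 2.0 * std::exp(-tau) / (4.0 * M_PI * d2);
                D.add(i, f, f * MEC2 * fine1_at(mu_air, MEC2), h);
              }
            }
            double u[3];
            iso_dir(u);
            if (nstack < 8) {
              stack[nstack][0] = pos[0]; stack[nstack][1] = pos[1];
              stack[nstack][2] = pos[2];
              stack[nstack][3] = -u[0]; stack[nstack][4] = -u[1];
              stack[nstack][5] = -u[2];
              stack[nstack][6] = MEC2;
              ++nstack;
            }
            dir[0] = u[0]; dir[1] = u[1]; dir[2] = u[2];
            E = MEC2;
          }
        } else {
          // boundary crossing
          double adv = tb + NUDGE;
          pos[0] += adv * dir[0]; pos[1] += adv * dir[1]; pos[2] += adv * dir[2];
        }
      }
      continue;
    next_photon:
      if (nstack > 0) {
        --nstack;
        pos[0] = stack[nstack][0]; pos[1] = stack[nstack][1];
        pos[2] = stack[nstack][2];
        dir[0] = stack[nstack][3]; dir[1] = stack[nstack][4];
        dir[2] = stack[nstack][5];
        E = stack[nstack][6];
        steps = 0;
      } else {
        have_photon = false;
      }
    }
  }

  if (have_tally) T.flush();
  if (have_det) D.flush();

  List out = List::create(
    _["n_histories"] = (double)n_hist,
    _["n_escaped"] = (double)n_escape,
    _["n_absorbed"] = (double)n_absorbed,
    _["n_cutoff"] = (double)n_cutoff);
  if (have_tally)
    out["cells"] = List::create(_["kerma_sum"] = wrap(T.k_sum),
                                _["kerma_ssq"] = wrap(T.k_ssq),
                                _["fluence_sum"] = wrap(T.f_sum),
                                _["fluence_ssq"] = wrap(T.f_ssq));
  if (have_det)
    out["detectors"] = List::create(_["fluence_sum"] = wrap(D.f_sum),
                                    _["kerma_sum"] = wrap(D.k_sum),
                                    _["kerma_ssq"] = wrap(D.k_ssq));
  if (have_spec) {
    NumericMatrix fl(S.ncell, S.nbin);
    for (int i = 0; i < S.ncell; ++i)
      for (int j = 0; j < S.nbin; ++j) fl(i, j) = S.flu[i + S.ncell * j];
    out["spectrum"] = fl;
  }
  return out;
}
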