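// Monte Carlo core: probabilistic neuropil generation, Brownian stepping with
// mirror reflections, transporter binding/unbinding bookkeeping.
// Units: micrometres and milliseconds throughout.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64. Self-contained so that runs are
// bit-identical across platforms for a given integer seed, independent of R's
// global RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1); never returns exactly 0
  inline double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }

  // standard normal, Box-Muller with spare caching
  inline double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Geometry
// ---------------------------------------------------------------------------

struct Capsule {
  // two solid hemispheres of radius R flanking the cleft void |z| <= hz,
  // rho <= R; hemisphere centres at (0, 0, +-hz)
  double R = 0.0, hz = 0.0;
  bool present = false;
};

struct Geometry {
  int n = 0;
  std::vector<double> cx, cy, cz, r;
  std::vector<int> role; // 0 neuronal, 1 astroglial
  double half = 2.0;     // arena half-width
  Capsule cap;

  // uniform grid over the arena; each cell lists spheres reachable from any
  // point in the cell within REACH (max step path length + proximity cutoff)
  double cell = 0.12;
  int ng = 1;
  std::vector<int> cell_start;
  std::vector<int> cell_ids;

  static constexpr double REACH = 0.05; // um

  inline int cell_index(double x, double y, double z) const {
    int ix = (int)((x + half) / cell); if (ix < 0) ix = 0; if (ix >= ng) ix = ng - 1;
    int iy = (int)((y + half) / cell); if (iy < 0) iy = 0; if (iy >= ng) iy = ng - 1;
    int iz = (int)((z + half) / cell); if (iz < 0) iz = 0; if (iz >= ng) iz = ng - 1;
    return (ix * ng + iy) * ng + iz;
  }

  void build_grid() {
    ng = std::max(1, (int)std::ceil(2.0 * half / cell));
    std::vector<std::vector<int>> tmp((size_t)ng * ng * ng);
    for (int i = 0; i < n; ++i) {
      double reach = r[i] + REACH;
      int ix0 = std::max(0, (int)std::floor((cx[i] - reach + half) / cell));
      int ix1 = std::min(ng - 1, (int)std::floor((cx[i] + reach + half) / cell));
      int iy0 = std::max(0, (int)std::floor((cy[i] - reach + half) / cell));
      int iy1 = std::min(ng - 1, (int)std::floor((cy[i] + reach + half) / cell));
      int iz0 = std::max(0, (int)std::floor((cz[i] - reach + half) / cell));
      int iz1 = std::min(ng - 1, (int)std::floor((cz[i] + reach + half) / cell));
      for (int ix = ix0; ix <= ix1; ++ix)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int iz = iz0; iz <= iz1; ++iz) {
            // min distance from sphere centre to the cell box
            double bx0 = -half + ix * cell, bx1 = bx0 + cell;
            double by0 = -half + iy * cell, by1 = by0 + cell;
            double bz0 = -half + iz * cell, bz1 = bz0 + cell;
            double dx = std::max({bx0 - cx[i], 0.0, cx[i] - bx1});
            double dy = std::max({by0 - cy[i], 0.0, cy[i] - by1});
            double dz = std::max({bz0 - cz[i], 0.0, cz[i] - bz1});
            if (dx * dx + dy * dy + dz * dz <= reach * reach)
              tmp[(size_t)(ix * ng + iy) * ng + iz].push_back(i);
          }
    }
    cell_start.assign(tmp.size() + 1, 0);
    size_t tot = 0;
    for (size_t c = 0; c < tmp.size(); ++c) { cell_start[c] = (int)tot; tot += tmp[c].size(); }
    cell_start[tmp.size()] = (int)tot;
    cell_ids.resize(tot);
    tot = 0;
    for (size_t c = 0; c < tmp.size(); ++c)
      for (int id : tmp[c]) cell_ids[tot++] = id;
  }
};

static Geometry make_geometry(const NumericMatrix& spheres, const IntegerVector& role,
                              double half, double capR, double capHz, bool capsule,
                              bool with_grid = true) {
  Geometry g;
  g.half = half;
  g.n = spheres.nrow();
  g.cx.resize(g.n); g.cy.resize(g.n); g.cz.resize(g.n); g.r.resize(g.n);
  g.role.resize(g.n);
  for (int i = 0; i < g.n; ++i) {
    g.cx[i] = spheres(i, 0); g.cy[i] = spheres(i, 1);
    g.cz[i] = spheres(i, 2); g.r[i] = spheres(i, 3);
    g.role[i] = (role.size() > i) ? role[i] : 0;
  }
  g.cap.present = capsule; g.cap.R = capR; g.cap.hz = capHz;
  if (with_grid) g.build_grid();
  return g;
}

// point-in-solid tests ------------------------------------------------------

static inline bool in_capsule_solid(const Capsule& c, double x, double y, double z) {
  if (!c.present) return false;
  if (z >= c.hz) {
    double dz = z - c.hz;
    return x * x + y * y + dz * dz <= c.R * c.R;
  }
  if (z <= -c.hz) {
    double dz = z + c.hz;
    return x * x + y * y + dz * dz <= c.R * c.R;
  }
  return false;
}

static inline bool in_listed_sphere(const Geometry& g, const int* ids, int nids,
                                    double x, double y, double z) {
  for (int k = 0; k < nids; ++k) {
    int i = ids[k];
    double dx = x - g.cx[i], dy = y - g.cy[i], dz = z - g.cz[i];
    if (dx * dx + dy * dy + dz * dz < g.r[i] * g.r[i]) return true;
  }
  return false;
}

// earliest segment-surface hit ----------------------------------------------

struct Hit {
  double t = 2.0;       // parameter along the segment, valid if <= 1
  double nx = 0, ny = 0, nz = 1; // outward surface normal at the hit point
  bool found = false;
};

static inline void consider_sphere(Hit& h, double cx, double cy, double cz, double R,
                                   double ox, double oy, double oz,
                                   double dx, double dy, double dz,
                                   double zlo, double zhi) {
  // segment o + t*d, t in (eps, 1]; zlo/zhi restrict the valid z band of the
  // spherical surface (used for hemispheric caps; +-inf for full spheres)
  double fx = ox - cx, fy = oy - cy, fz = oz - cz;
  double a = dx * dx + dy * dy + dz * dz;
  if (a <= 0.0) return;
  double b = 2.0 * (fx * dx + fy * dy + fz * dz);
  double c = fx * fx + fy * fy + fz * fz - R * R;
  if (c <= 0.0) return; // start on/inside: no entering hit
  double disc = b * b - 4.0 * a * c;
  if (disc <= 0.0) return;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / (2.0 * a); // entering root
  if (t1 <= 1e-12 || t1 > 1.0 || t1 >= h.t) return;
  double hz_ = oz + t1 * dz;
  if (hz_ < zlo || hz_ > zhi) return;
  double hx = ox + t1 * dx, hy = oy + t1 * dy;
  h.t = t1; h.found = true;
  h.nx = (hx - cx) / R; h.ny = (hy - cy) / R; h.nz = (hz_ - cz) / R;
}

static inline void consider_plane(Hit& h, int axis, double level, double dir,
                                  double ox, double oy, double oz,
                                  double dx, double dy, double dz,
                                  double rho_max) {
  // plane {axis coord == level}, solid on the side sign(dir); valid only where
  // the in-plane radius from the z-axis is <= rho_max (rho_max < 0: no limit)
  double o = (axis == 0) ? ox : (axis == 1) ? oy : oz;
  double d = (axis == 0) ? dx : (axis == 1) ? dy : dz;
  if (d * dir <= 0.0) return;        // moving away from the solid side
  if ((level - o) * dir <= 0.0) return; // already past the plane
  double t1 = (level - o) / d;
  if (t1 <= 1e-12 || t1 > 1.0 || t1 >= h.t) return;
  if (rho_max >= 0.0) {
    double hx = ox + t1 * dx, hy = oy + t1 * dy;
    if (hx * hx + hy * hy > rho_max * rho_max) return;
  }
  h.t = t1; h.found = true;
  h.nx = h.ny = h.nz = 0.0;
  if (axis == 0) h.nx = -dir; else if (axis == 1) h.ny = -dir; else h.nz = -dir;
}

// Iterative mirror reflection of a step segment against the listed spheres,
// the cleft capsule (if near) and the arena walls (if near). Returns the
// corrected endpoint; `ok = false` if the cascade did not converge.
static inline void reflect_segment(const Geometry& g, const int* ids, int nids,
                                   bool check_cap, bool check_walls,
                                   bool open_boundary,
                                   double ox, double oy, double oz,
                                   double& px, double& py, double& pz,
                                   bool& ok, bool& escaped, int max_iter = 8) {
  escaped = false;
  ok = true;
  double cx_ = ox, cy_ = oy, cz_ = oz; // current segment origin
  for (int iter = 0; iter < max_iter; ++iter) {
    double dx = px - cx_, dy = py - cy_, dz = pz - cz_;
    Hit h;
    for (int k = 0; k < nids; ++k) {
      int i = ids[k];
      consider_sphere(h, g.cx[i], g.cy[i], g.cz[i], g.r[i],
                      cx_, cy_, cz_, dx, dy, dz, -1e30, 1e30);
    }
    if (check_cap && g.cap.present) {
      // flat faces of the hemispheric obstacles (cleft floor/ceiling)
      consider_plane(h, 2,  g.cap.hz, +1.0, cx_, cy_, cz_, dx, dy, dz, g.cap.R);
      consider_plane(h, 2, -g.cap.hz, -1.0, cx_, cy_, cz_, dx, dy, dz, g.cap.R);
      // spherical caps
      consider_sphere(h, 0.0, 0.0,  g.cap.hz, g.cap.R, cx_, cy_, cz_, dx, dy, dz,
                      g.cap.hz, 1e30);
      consider_sphere(h, 0.0, 0.0, -g.cap.hz, g.cap.R, cx_, cy_, cz_, dx, dy, dz,
                      -1e30, -g.cap.hz);
    }
    if (check_walls) {
      if (open_boundary) {
        if (px < -g.half || px > g.half || py < -g.half || py > g.half ||
            pz < -g.half || pz > g.half) {
          // only escape if no solid surface is hit first
          if (!h.found) { escaped = true; return; }
        }
      } else {
        consider_plane(h, 0,  g.half, +1.0, cx_, cy_, cz_, dx, dy, dz, -1.0);
        consider_plane(h, 0, -g.half, -1.0, cx_, cy_, cz_, dx, dy, dz, -1.0);
        consider_plane(h, 1,  g.half, +1.0, cx_, cy_, cz_, dx, dy, dz, -1.0);
        consider_plane(h, 1, -g.half, -1.0, cx_, cy_, cz_, dx, dy, dz, -1.0);
        consider_plane(h, 2,  g.half, +1.0, cx_, cy_, cz_, dx, dy, dz, -1.0);
        consider_plane(h, 2, -g.half, -1.0, cx_, cy_, cz_, dx, dy, dz, -1.0);
      }
    }

    if (!h.found) {
      // endpoint must be valid; if not (tunnelled past a surface at grazing
      // incidence), signal failure
      bool bad = in_listed_sphere(g, ids, nids, px, py, pz) ||
                 in_capsule_solid(g.cap, px, py, pz);
      if (!open_boundary)
        bad = bad || px < -g.half || px > g.half || py < -g.half ||
              py > g.half || pz < -g.half || pz > g.half;
      ok = !bad;
      return;
    }

    // reflect the remainder of the segment about the tangent plane
    double hx = cx_ + h.t * dx, hy = cy_ + h.t * dy, hzp = cz_ + h.t * dz;
    double rx = (1.0 - h.t) * dx, ry = (1.0 - h.t) * dy, rz = (1.0 - h.t) * dz;
    double dot = rx * h.nx + ry * h.ny + rz * h.nz;
    rx -= 2.0 * dot * h.nx; ry -= 2.0 * dot * h.ny; rz -= 2.0 * dot * h.nz;
    // nudge off the surface to avoid immediate re-hit from rounding
    cx_ = hx + 1e-9 * h.nx; cy_ = hy + 1e-9 * h.ny; cz_ = hzp + 1e-9 * h.nz;
    px = cx_ + rx; py = cy_ + ry; pz = cz_ + rz;
  }
  // did not settle
  ok = !(in_listed_sphere(g, ids, nids, px, py, pz) ||
         in_capsule_solid(g.cap, px, py, pz) ||
         (!open_boundary && (px < -g.half || px > g.half || py < -g.half ||
                             py > g.half || pz < -g.half || pz > g.half)));
}

// ---------------------------------------------------------------------------
// Environment generation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_generate_environment(double edge, double alpha_target, double vf_target,
                              double r_min, double r_max, double cap_R, double cap_hz,
                              double min_gap, int n_points, double role_tol,
                              int max_spheres, double seed) {
  Xoshiro rng((uint64_t)seed);
  double half = edge / 2.0;

  // fixed internal test points; per-point deepest-containment owner
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  std::vector<double> depth(n_points, -1.0); // best penetration depth (r - dist)
  std::vector<int> owner(n_points, -1);      // sphere index, -2 = cleft obstacle
  Capsule cap; cap.present = true; cap.R = cap_R; cap.hz = cap_hz;
  int covered = 0;
  for (int p = 0; p < n_points; ++p) {
    px[p] = (rng.unif() * 2.0 - 1.0) * half;
    py[p] = (rng.unif() * 2.0 - 1.0) * half;
    pz[p] = (rng.unif() * 2.0 - 1.0) * half;
    if (in_capsule_solid(cap, px[p], py[p], pz[p])) {
      owner[p] = -2; depth[p] = 1e30; ++covered;
    }
  }

  // bucket the test points into a uniform grid so each candidate sphere only
  // visits points near it
  double pcell = 0.1;
  int png = std::max(1, (int)std::ceil(edge / pcell));
  std::vector<std::vector<int>> buckets((size_t)png * png * png);
  auto bidx = [&](double vx, double vy, double vz) {
    int ix = std::min(png - 1, std::max(0, (int)((vx + half) / pcell)));
    int iy = std::min(png - 1, std::max(0, (int)((vy + half) / pcell)));
    int iz = std::min(png - 1, std::max(0, (int)((vz + half) / pcell)));
    return (size_t)(ix * png + iy) * png + iz;
  };
  for (int p = 0; p < n_points; ++p) buckets[bidx(px[p], py[p], pz[p])].push_back(p);

  std::vector<double> sx, sy, sz, sr;
  double alpha_hat = 1.0 - (double)covered / n_points;
  double cap_excl = cap_R + min_gap; // centre-to-axis-segment clearance base

  while (alpha_hat > alpha_target) {
    if ((int)sx.size() >= max_spheres)
      stop("volume-fraction target alpha=%.3f not reached after %d spheres "
           "(measured alpha=%.4f); check radius range and targets",
           alpha_target, max_spheres, alpha_hat);
    double x = (rng.unif() * 2.0 - 1.0) * half;
    double y = (rng.unif() * 2.0 - 1.0) * half;
    double z = (rng.unif() * 2.0 - 1.0) * half;
    double r = r_min + (r_max - r_min) * rng.unif();
    // clearance to the cleft capsule: distance from centre to the axis
    // segment z in [-hz, hz] must exceed cap_R + min_gap + r
    double dzc = std::fabs(z) <= cap_hz ? 0.0 : std::fabs(z) - cap_hz;
    double dax = std::sqrt(x * x + y * y + dzc * dzc);
    if (dax < cap_excl + r) continue; // reject: violates cleft gap

    int i = (int)sx.size();
    sx.push_back(x); sy.push_back(y); sz.push_back(z); sr.push_back(r);
    // update ownership of points near this sphere
    int ix0 = std::max(0, (int)((x - r + half) / pcell));
    int ix1 = std::min(png - 1, (int)((x + r + half) / pcell));
    int iy0 = std::max(0, (int)((y - r + half) / pcell));
    int iy1 = std::min(png - 1, (int)((y + r + half) / pcell));
    int iz0 = std::max(0, (int)((z - r + half) / pcell));
    int iz1 = std::min(png - 1, (int)((z + r + half) / pcell));
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int iz = iz0; iz <= iz1; ++iz)
          for (int p : buckets[(size_t)(ix * png + iy) * png + iz]) {
            double ddx = px[p] - x, ddy = py[p] - y, ddz = pz[p] - z;
            double dist2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (dist2 < r * r) {
              double dep = r - std::sqrt(dist2);
              if (owner[p] == -1) ++covered;
              if (dep > depth[p] && owner[p] != -2) { depth[p] = dep; owner[p] = i; }
            }
          }
    alpha_hat = 1.0 - (double)covered / n_points;
  }

  int n_sph = (int)sx.size();
  // role assignment: Bernoulli at p0 = VF / solid fraction, then greedy label
  // flips against the measured astro share until within role_tol
  std::vector<int> role(n_sph, 0);
  std::vector<int> pts_per_sphere(n_sph, 0);
  for (int p = 0; p < n_points; ++p)
    if (owner[p] >= 0) ++pts_per_sphere[owner[p]];
  double solid = 1.0 - alpha_hat;
  double p0 = solid > 0 ? std::min(1.0, vf_target / solid) : 0.0;
  long astro_pts = 0;
  for (int i = 0; i < n_sph; ++i) {
    if (vf_target > 0 && rng.unif() < p0) { role[i] = 1; astro_pts += pts_per_sphere[i]; }
  }
  double vf_hat = (double)astro_pts / n_points;
  if (vf_target > 0 && n_sph > 0) {
    long target_pts = (long)std::llround(vf_target * n_points);
    long tol_pts = (long)std::llround(role_tol * n_points);
    int tries = 0, max_tries = 60 * n_sph;
    while (std::labs(astro_pts - target_pts) > tol_pts && tries++ < max_tries) {
      int i = (int)(rng.unif() * n_sph); if (i >= n_sph) i = n_sph - 1;
      long delta = pts_per_sphere[i];
      if (astro_pts < target_pts && role[i] == 0) { role[i] = 1; astro_pts += delta; }
      else if (astro_pts > target_pts && role[i] == 1) { role[i] = 0; astro_pts -= delta; }
    }
    vf_hat = (double)astro_pts / n_points;
  }

  NumericMatrix spheres(n_sph, 4);
  IntegerVector role_out(n_sph);
  for (int i = 0; i < n_sph; ++i) {
    spheres(i, 0) = sx[i]; spheres(i, 1) = sy[i];
    spheres(i, 2) = sz[i]; spheres(i, 3) = sr[i];
    role_out[i] = role[i];
  }
  return List::create(_["spheres"] = spheres, _["role"] = role_out,
                      _["alpha_hat"] = alpha_hat, _["vf_astro_hat"] = vf_hat,
                      _["n_points"] = n_points);
}

// ---------------------------------------------------------------------------
// Point classification (deepest-containment ownership, ties -> lowest index)
// labels: 0 extracellular, 1 neuronal, 2 astroglial, 3 cleft obstacle
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_classify_points(NumericMatrix spheres, IntegerVector role,
                                  NumericMatrix pts, double half,
                                  double cap_R, double cap_hz, bool capsule) {
  Geometry g = make_geometry(spheres, role, half, cap_R, cap_hz, capsule);
  int m = pts.nrow();
  IntegerVector lab(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (in_capsule_solid(g.cap, x, y, z)) { lab[p] = 3; continue; }
    int cidx = g.cell_index(x, y, z);
    const int* ids = g.cell_ids.data() + g.cell_start[cidx];
    int nids = g.cell_start[cidx + 1] - g.cell_start[cidx];
    // candidates are listed in increasing sphere index, so a strict
    // comparison implements the lowest-index tie-break
    double best = 0.0; int who = -1;
    for (int k = 0; k < nids; ++k) {
      int i = ids[k];
      double dx = x - g.cx[i], dy = y - g.cy[i], dz = z - g.cz[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= g.r[i] * g.r[i]) continue;
      double dep = g.r[i] - std::sqrt(d2);
      if (dep > best) { best = dep; who = i; }
    }
    lab[p] = (who < 0) ? 0 : (g.role[who] == 1 ? 2 : 1);
  }
  return lab;
}

// [[Rcpp::export]]
NumericVector cpp_nearest_astro_dist(NumericMatrix spheres, IntegerVector role,
                                     NumericMatrix pts, double half) {
  // exact brute-force distance to the nearest astroglial surface (no grid
  // reach limit): used by the R-level astro_proximity surface
  int m = pts.nrow(), n = spheres.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      if (role[i] != 1) continue;
      double dx = pts(p, 0) - spheres(i, 0);
      double dy = pts(p, 1) - spheres(i, 1);
      double dz = pts(p, 2) - spheres(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - spheres(i, 3);
      if (d < best) best = d;
    }
    out[p] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Stand-alone collision resolution (R-level surface); brute force over all
// spheres, so arbitrary segment lengths are allowed
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_resolve_collisions(NumericMatrix spheres, IntegerVector role,
                            NumericMatrix old_pos, NumericMatrix new_pos,
                            double half, double cap_R, double cap_hz,
                            bool capsule, bool open_boundary) {
  Geometry g = make_geometry(spheres, role, half, cap_R, cap_hz, capsule,
                             /*with_grid=*/false);
  std::vector<int> all_ids(g.n);
  for (int i = 0; i < g.n; ++i) all_ids[i] = i;
  int n = old_pos.nrow();
  NumericMatrix out(n, 3);
  LogicalVector converged(n), escaped_v(n);
  for (int p = 0; p < n; ++p) {
    double px = new_pos(p, 0), py = new_pos(p, 1), pz = new_pos(p, 2);
    bool ok, esc;
    reflect_segment(g, all_ids.data(), g.n, true, true, open_boundary,
                    old_pos(p, 0), old_pos(p, 1), old_pos(p, 2),
                    px, py, pz, ok, esc);
    out(p, 0) = px; out(p, 1) = py; out(p, 2) = pz;
    converged[p] = ok; escaped_v[p] = esc;
  }
  return List::create(_["positions"] = out, _["converged"] = converged,
                      _["escaped"] = escaped_v);
}

// ---------------------------------------------------------------------------
// Main simulation loop
// status codes: 0 free, 1 bound (release scheduled), 2 retained (translocation
// fate), 3 escaped (open boundary only)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix spheres, IntegerVector role,
                  double half, double cap_R, double cap_hz, bool capsule,
                  int n_particles, double release_R, double release_hz,
                  double D, double dt, double t_end, NumericVector record_t,
                  double psi, double p_unbind, double unbind_mu,
                  double unbind_sigma, double cutoff, bool binding_enabled,
                  bool open_boundary, double seed) {
  Geometry g = make_geometry(spheres, role, half, cap_R, cap_hz, capsule);

  // 3D step length clamp: rare extreme Gaussian draws are rescaled so the
  // candidate shortlist (grid REACH) provably covers every possible path
  const double L_max = 3.5 * std::sqrt(6.0 * D * dt); // P(exceed) ~ 5e-8
  if (g.n > 0 && L_max + cutoff > Geometry::REACH)
    stop("time step too large for the collision grid: reduce dt so that "
         "3.5*sqrt(6 D dt) + cutoff <= %.3f um", Geometry::REACH);

  // one RNG sub-stream per particle, counter-derived from the run seed, so
  // that paired conditions (e.g. unbinding on/off with a shared seed) give
  // each particle identical diffusion noise until its own fate diverges
  std::vector<Xoshiro> rngs;
  rngs.reserve(n_particles);
  for (int p = 0; p < n_particles; ++p)
    rngs.emplace_back((uint64_t)seed * 0x9E3779B97F4A7C15ULL + (uint64_t)(p + 1));

  std::vector<double> x(n_particles), y(n_particles), z(n_particles);
  std::vector<int> status(n_particles, 0);
  std::vector<double> clock_(n_particles, 0.0), rel_t(n_particles, 0.0);

  // uniform release inside the cylinder rho <= release_R, |z| <= release_hz
  for (int p = 0; p < n_particles; ++p) {
    Xoshiro& rng = rngs[p];
    double rr = release_R * std::sqrt(rng.unif());
    double th = 2.0 * M_PI * rng.unif();
    x[p] = rr * std::cos(th);
    y[p] = rr * std::sin(th);
    z[p] = (rng.unif() * 2.0 - 1.0) * release_hz;
  }

  long n_steps = (long)std::llround(t_end / dt);
  int n_rec = record_t.size();
  std::vector<long> rec_step(n_rec);
  for (int k = 0; k < n_rec; ++k)
    rec_step[k] = std::min(n_steps, (long)std::llround(record_t[k] / dt));

  List pos_out(n_rec);
  IntegerMatrix status_out(n_particles, n_rec);
  NumericVector times_out(n_rec);

  const double sd_step = std::sqrt(2.0 * D * dt);
  const double h_bind = (psi > 0.0) ? 1.0 - std::exp(-dt / psi) : 1.0;
  const double wall_margin = half - (L_max + 1e-6);
  const double cap_near2 = (cap_R + cap_hz + L_max + 1e-6) *
                           (cap_R + cap_hz + L_max + 1e-6);
  long n_bind = 0, n_release = 0, n_reject = 0, n_escape = 0;
  int rec_k = 0;
  bool astro_present = false;
  for (int i = 0; i < g.n; ++i) if (g.role[i] == 1) { astro_present = true; break; }
  bool do_binding = binding_enabled && astro_present && psi > 0.0;

  auto take_record = [&](int k, double tnow) {
    NumericMatrix m(n_particles, 3);
    for (int p = 0; p < n_particles; ++p) {
      m(p, 0) = x[p]; m(p, 1) = y[p]; m(p, 2) = z[p];
      status_out(p, k) = status[p];
    }
    pos_out[k] = m;
    times_out[k] = tnow;
  };
  while (rec_k < n_rec && rec_step[rec_k] == 0) { take_record(rec_k, 0.0); ++rec_k; }

  int short_ids[256];
  int astro_ids[256];

  for (long s = 1; s <= n_steps; ++s) {
    double t_now = s * dt;
    for (int p = 0; p < n_particles; ++p) {
      int st = status[p];
      if (st == 3 || st == 2) continue; // escaped / retained: inert
      if (st == 1) {
        if (t_now >= rel_t[p]) { status[p] = 0; clock_[p] = 0.0; ++n_release; }
        continue; // released particles move again from the next step
      }
      // free particle: Brownian proposal
      Xoshiro& rng = rngs[p];
      double gx = rng.gauss() * sd_step, gy = rng.gauss() * sd_step,
             gz = rng.gauss() * sd_step;
      double L2 = gx * gx + gy * gy + gz * gz;
      if (L2 > L_max * L_max) {
        double f = L_max / std::sqrt(L2);
        gx *= f; gy *= f; gz *= f;
      }
      double ox = x[p], oy = y[p], oz = z[p];
      double pxn = ox + gx, pyn = oy + gy, pzn = oz + gz;

      // shortlist of spheres reachable along this step (plus proximity band)
      int cidx = g.cell_index(ox, oy, oz);
      const int* ids = g.cell_ids.data() + g.cell_start[cidx];
      int nids = g.cell_start[cidx + 1] - g.cell_start[cidx];
      int ns = 0, na = 0;
      for (int k = 0; k < nids; ++k) {
        int i = ids[k];
        double dxc = ox - g.cx[i], dyc = oy - g.cy[i], dzc = oz - g.cz[i];
        double d2 = dxc * dxc + dyc * dyc + dzc * dzc;
        double rb = g.r[i] + L_max;
        if (g.role[i] == 1) {
          double ra = rb + cutoff;
          if (d2 <= ra * ra && na < 256) {
            astro_ids[na++] = i;
            if (d2 <= rb * rb && ns < 256) short_ids[ns++] = i;
          }
        } else if (d2 <= rb * rb && ns < 256) {
          short_ids[ns++] = i;
        }
      }
      bool near_wall = std::fabs(ox) > wall_margin || std::fabs(oy) > wall_margin ||
                       std::fabs(oz) > wall_margin;
      bool near_cap = g.cap.present &&
                      (ox * ox + oy * oy + oz * oz) < cap_near2;

      if (ns > 0 || near_wall || near_cap) {
        bool ok, esc;
        reflect_segment(g, short_ids, ns, near_cap, near_wall, open_boundary,
                        ox, oy, oz, pxn, pyn, pzn, ok, esc);
        if (esc) { status[p] = 3; ++n_escape; continue; }
        if (!ok) { ++n_reject; continue; } // revert: keep old position
      }
      x[p] = pxn; y[p] = pyn; z[p] = pzn;

      if (!do_binding) continue;
      if (na == 0) { clock_[p] = 0.0; continue; }
      double dist = 1e30;
      for (int k = 0; k < na; ++k) {
        int i = astro_ids[k];
        double dxc = pxn - g.cx[i], dyc = pyn - g.cy[i], dzc = pzn - g.cz[i];
        double d = std::sqrt(dxc * dxc + dyc * dyc + dzc * dzc) - g.r[i];
        if (d < dist) dist = d;
      }
      if (dist <= cutoff) {
        clock_[p] += dt;
        if (rng.unif() < h_bind) {
          ++n_bind;
          // fate and delay draws are always consumed, keeping the particle's
          // stream aligned between p_unbind settings
          double u_fate = rng.unif();
          double delay = unbind_mu + unbind_sigma * rng.gauss();
          if (u_fate < p_unbind) {
            status[p] = 1;
            if (delay < 0.0) delay = 0.0; // censor: atom at zero delay
            rel_t[p] = t_now + delay;
          } else {
            status[p] = 2; // translocation fate: retained for the whole run
          }
        }
      } else {
        clock_[p] = 0.0; // proximity clock resets once > cutoff away
      }
    }
    while (rec_k < n_rec && rec_step[rec_k] == s) { take_record(rec_k, t_now); ++rec_k; }
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = times_out, _["positions"] = pos_out,
                      _["status"] = status_out,
                      _["counters"] = List::create(
                        _["n_bind_events"] = (double)n_bind,
                        _["n_release_events"] = (double)n_release,
                        _["n_rejected_moves"] = (double)n_reject,
                        _["n_escaped"] = (double)n_escape));
}
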