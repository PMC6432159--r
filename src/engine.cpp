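// Force kernels and Langevin integrator for the driven-translocation model.
//
// Geometry convention (package-wide): pore axis = z, wall centered at z = 0,
// trans side = +z.  x and y are always periodic; z optionally.  All numbers
// are in reduced units (sigma, kBT, e, m, tau_u).
//
// Interactions: WCA excluded volume (mobile-mobile and mobile-wall),
// harmonic bonds, Coulomb electrostatics (direct truncated-shifted or
// Debye-Hueckel screened, minimum image), uniform field -E z^ acting on
// charges inside the pore slab |z| <= wall_half, and a half-space WCA gate
// on the head monomer that diverges at the pore-exit plane.
//
// Integrator: BAOAB splitting of underdamped Langevin dynamics.  With
// zeta = 0 the O-step is the identity and the scheme reduces exactly to
// velocity Verlet, so the zero-friction energy-conservation check applies
// to the very code path used in production.  Random numbers come from R's
// RNG so that set.seed() governs the whole simulation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Par {
  double box_x, box_y, box_z;
  bool periodic_z;
  double wall_half;
  double k, l0;
  double sigma_bb, eps_bb, sigma_bw, eps_bw;
  double lambda_B;
  int coul_mode;           // 0 none, 1 direct truncated-shifted, 2 screened
  double r_cut, screen_len;
  double E;
  bool gate_on;
  double gate_z, gate_sigma, gate_eps;
  int head;                // 0-based index of the head monomer
  double dt, zeta, mass, kBT;
};

static Par read_par(const List& p) {
  Par q;
  q.box_x = p["box_x"]; q.box_y = p["box_y"]; q.box_z = p["box_z"];
  q.periodic_z = p["periodic_z"];
  q.wall_half = p["wall_half"];
  q.k = p["k"]; q.l0 = p["l0"];
  q.sigma_bb = p["sigma_bb"]; q.eps_bb = p["eps_bb"];
  q.sigma_bw = p["sigma_bw"]; q.eps_bw = p["eps_bw"];
  q.lambda_B = p["lambda_B"];
  q.coul_mode = p["coul_mode"];
  q.r_cut = p["r_cut"]; q.screen_len = p["screen_len"];
  q.E = p["E"];
  q.gate_on = p["gate_on"];
  q.gate_z = p["gate_z"]; q.gate_sigma = p["gate_sigma"];
  q.gate_eps = p["gate_eps"];
  q.head = p["head"];
  q.dt = p["dt"]; q.zeta = p["zeta"]; q.mass = p["mass"]; q.kBT = p["kBT"];
  return q;
}

static inline void min_image(double& dx, double& dy, double& dz,
                             const Par& p) {
  dx -= p.box_x * std::round(dx / p.box_x);
  dy -= p.box_y * std::round(dy / p.box_y);
  if (p.periodic_z) dz -= p.box_z * std::round(dz / p.box_z);
}

// WCA pair: returns energy, adds force magnitude/r (i.e. f/r) to fr.
static inline double wca_pair(double r2, double sig, double eps, double& fr) {
  double rc2 = std::pow(2.0, 1.0 / 3.0) * sig * sig; // (2^(1/6) sig)^2
  if (r2 >= rc2) { fr = 0.0; return 0.0; }
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  fr = 24.0 * eps * (2.0 * s12 - s6) / r2;
  return 4.0 * eps * (s12 - s6) + eps;
}

// Coulomb pair (direct shifted or screened shifted); fr gets f/r.
static inline double coul_pair(double r2, double qq, const Par& p,
                               double& fr) {
  fr = 0.0;
  if (p.coul_mode == 0 || qq == 0.0) return 0.0;
  if (r2 >= p.r_cut * p.r_cut) return 0.0;
  double r = std::sqrt(r2);
  double pref = p.lambda_B * p.kBT * qq;
  if (p.coul_mode == 1) {
    double shift = (std::isfinite(p.r_cut)) ? pref / p.r_cut : 0.0;
    fr = pref / (r2 * r);
    return pref / r - shift;
  }
  double ex = std::exp(-r / p.screen_len);
  double shift = std::isfinite(p.r_cut)
    ? pref * std::exp(-p.r_cut / p.screen_len) / p.r_cut : 0.0;
  fr = pref * ex * (1.0 / r2 + 1.0 / (r * p.screen_len)) / r;
  return pref * ex / r - shift;
}

// Static cell grid over the wall beads (x-y periodic).
struct WallGrid {
  double cell; int nx, ny;
  double zmin, zmax;
  std::vector< std::vector<int> > bins;
  void build(const NumericMatrix& wall, const Par& p, double rc) {
    cell = std::max(rc, 1e-3);
    nx = std::max(1, (int)std::floor(p.box_x / cell));
    ny = std::max(1, (int)std::floor(p.box_y / cell));
    bins.assign((size_t)nx * ny, std::vector<int>());
    zmin = 1e300; zmax = -1e300;
    for (int i = 0; i < wall.nrow(); ++i) {
      double x = wall(i, 0) - p.box_x * std::floor(wall(i, 0) / p.box_x);
      double y = wall(i, 1) - p.box_y * std::floor(wall(i, 1) / p.box_y);
      int cx = std::min(nx - 1, (int)(x / p.box_x * nx));
      int cy = std::min(ny - 1, (int)(y / p.box_y * ny));
      bins[(size_t)cx * ny + cy].push_back(i);
      zmin = std::min(zmin, wall(i, 2)); zmax = std::max(zmax, wall(i, 2));
    }
  }
};

// Full force evaluation.  Returns potential energy if want_energy.
static double forces(const NumericMatrix& pos, const NumericVector& charge,
                     const IntegerMatrix& bonds, const NumericMatrix& wall,
                     const WallGrid& grid, const Par& p, int n_mono,
                     NumericMatrix& F, bool want_energy) {
  int n = pos.nrow();
  double U = 0.0;
  std::fill(F.begin(), F.end(), 0.0);

  bool any_coul = (p.coul_mode != 0);
  double rc_bb = std::pow(2.0, 1.0 / 6.0) * p.sigma_bb;
  double rmax = rc_bb;
  if (any_coul) rmax = std::max(rmax, p.r_cut);
  double rmax2 = std::isfinite(rmax) ? rmax * rmax : 1e300;

  // mobile-mobile: WCA + electrostatics
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      min_image(dx, dy, dz, p);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rmax2) continue;
      if (r2 < 1e-12) stop("overlapping beads (r < 1e-6) at pair %d,%d",
                           i + 1, j + 1);
      double fr1, fr2;
      double u1 = wca_pair(r2, p.sigma_bb, p.eps_bb, fr1);
      double u2 = coul_pair(r2, charge[i] * charge[j], p, fr2);
      double fr = fr1 + fr2;
      if (want_energy) U += u1 + u2;
      if (fr != 0.0) {
        F(i, 0) += fr * dx; F(i, 1) += fr * dy; F(i, 2) += fr * dz;
        F(j, 0) -= fr * dx; F(j, 1) -= fr * dy; F(j, 2) -= fr * dz;
      }
    }
  }

  // bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    min_image(dx, dy, dz, p);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dl = r - p.l0;
    if (want_energy) U += 0.5 * p.k * dl * dl;
    double fr = -p.k * dl / std::max(r, 1e-12);
    F(i, 0) += fr * dx; F(i, 1) += fr * dy; F(i, 2) += fr * dz;
    F(j, 0) -= fr * dx; F(j, 1) -= fr * dy; F(j, 2) -= fr * dz;
  }

  // mobile-wall WCA via the cell grid
  if (wall.nrow() > 0) {
    double rc_bw = std::pow(2.0, 1.0 / 6.0) * p.sigma_bw;
    for (int i = 0; i < n; ++i) {
      double z = pos(i, 2);
      if (z < grid.zmin - rc_bw || z > grid.zmax + rc_bw) continue;
      double x = pos(i, 0) - p.box_x * std::floor(pos(i, 0) / p.box_x);
      double y = pos(i, 1) - p.box_y * std::floor(pos(i, 1) / p.box_y);
      int cx = std::min(grid.nx - 1, (int)(x / p.box_x * grid.nx));
      int cy = std::min(grid.ny - 1, (int)(y / p.box_y * grid.ny));
      for (int ox = -1; ox <= 1; ++ox) {
        for (int oy = -1; oy <= 1; ++oy) {
          int gx = (cx + ox + grid.nx) % grid.nx;
          int gy = (cy + oy + grid.ny) % grid.ny;
          const std::vector<int>& bin = grid.bins[(size_t)gx * grid.ny + gy];
          for (size_t m = 0; m < bin.size(); ++m) {
            int w = bin[m];
            double dx = pos(i, 0) - wall(w, 0);
            double dy = pos(i, 1) - wall(w, 1);
            double dz = pos(i, 2) - wall(w, 2);
            min_image(dx, dy, dz, p);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= rc_bw * rc_bw) continue;
            if (r2 < 1e-12) stop("mobile bead %d overlaps a wall bead", i + 1);
            double fr;
            double u = wca_pair(r2, p.sigma_bw, p.eps_bw, fr);
            if (want_energy) U += u;
            F(i, 0) += fr * dx; F(i, 1) += fr * dy; F(i, 2) += fr * dz;
          }
        }
      }
    }
  }

  // driving field inside the pore slab: force q * (-E) z^.  The potential
  // is q*E*clamp(z, -wall_half, wall_half): linear in the slab, constant
  // outside, so the force is its exact (continuous-potential) gradient.
  if (p.E != 0.0) {
    for (int i = 0; i < n; ++i) {
      if (charge[i] == 0.0) continue;
      double z = pos(i, 2);
      if (std::fabs(z) <= p.wall_half) F(i, 2) += charge[i] * (-p.E);
      if (want_energy) {
        double zc = std::min(std::max(z, -p.wall_half), p.wall_half);
        U += charge[i] * p.E * zc;
      }
    }
  }

  // exit gate on the head monomer: WCA wall in z, divergent at gate_z
  if (p.gate_on) {
    double rc_g = std::pow(2.0, 1.0 / 6.0) * p.gate_sigma;
    double d = pos(p.head, 2) - p.gate_z;
    if (d < rc_g) {
      double dd = std::max(d, 1e-9);
      double fr;
      double u = wca_pair(dd * dd, p.gate_sigma, p.gate_eps, fr);
      if (want_energy) U += u;
      F(p.head, 2) += fr * dd;   // repulsion along +z
    }
  }

  return U;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector charge, IntegerMatrix bonds,
                NumericMatrix wall, List par, int n_mono) {
  Par p = read_par(par);
  WallGrid grid;
  if (wall.nrow() > 0)
    grid.build(wall, p, std::pow(2.0, 1.0 / 6.0) * p.sigma_bw);
  NumericMatrix F(pos.nrow(), 3);
  double U = forces(pos, charge, bonds, wall, grid, p, n_mono, F, true);
  return List::create(_["energy"] = U, _["forces"] = F);
}

static inline int count_trans(const NumericMatrix& pos, int n_mono,
                              double wall_half) {
  int s = 0;
  for (int i = 0; i < n_mono; ++i) if (pos(i, 2) > wall_half) ++s;
  return s;
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector charge,
             IntegerMatrix bonds, NumericMatrix wall, List par,
             int n_mono, int nsteps, int stride, bool constrain_head,
             bool stop_at_completion, bool record_s) {
  Par p = read_par(par);
  int n = pos.nrow();
  WallGrid grid;
  if (wall.nrow() > 0)
    grid.build(wall, p, std::pow(2.0, 1.0 / 6.0) * p.sigma_bw);

  NumericMatrix x = clone(pos), v = clone(vel);
  NumericMatrix F(n, 3);
  forces(x, charge, bonds, wall, grid, p, n_mono, F, false);

  double c1 = (p.zeta > 0.0) ? std::exp(-p.zeta / p.mass * p.dt) : 1.0;
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) *
              std::sqrt(p.kBT / p.mass);
  double half_dt_m = 0.5 * p.dt / p.mass;

  std::vector<int> s_series;
  if (record_s) s_series.reserve(nsteps);
  std::vector<NumericMatrix> frames;
  std::vector<double> frame_steps;

  GetRNGstate();
  int step = 0;
  bool completed = false;
  for (step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      if (constrain_head && i == p.head) continue;
      for (int a = 0; a < 3; ++a) v(i, a) += half_dt_m * F(i, a);
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (constrain_head && i == p.head) continue;
      for (int a = 0; a < 3; ++a) x(i, a) += 0.5 * p.dt * v(i, a);
    }
    // O
    if (p.zeta > 0.0) {
      for (int i = 0; i < n; ++i) {
        if (constrain_head && i == p.head) continue;
        for (int a = 0; a < 3; ++a)
          v(i, a) = c1 * v(i, a) + c2 * norm_rand();
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      if (constrain_head && i == p.head) continue;
      for (int a = 0; a < 3; ++a) x(i, a) += 0.5 * p.dt * v(i, a);
    }
    // B with fresh forces
    forces(x, charge, bonds, wall, grid, p, n_mono, F, false);
    for (int i = 0; i < n; ++i) {
      if (constrain_head && i == p.head) continue;
      for (int a = 0; a < 3; ++a) v(i, a) += half_dt_m * F(i, a);
    }

    if (!R_finite(x(0, 2)) || !R_finite(x(n - 1, 2))) {
      PutRNGstate();
      stop("integration became unstable at step %d (non-finite coordinate); "
           "reduce dt", step);
    }

    int s = -1;
    if (record_s || stop_at_completion) s = count_trans(x, n_mono, p.wall_half);
    if (record_s) s_series.push_back(s);
    if (stride > 0 && (step % stride == 0)) {
      frames.push_back(clone(x));
      frame_steps.push_back((double)step);
    }
    if (stop_at_completion && s == n_mono) { completed = true; break; }
  }
  PutRNGstate();
  int steps_done = std::min(step, nsteps);

  List fr(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) fr[i] = frames[i];
  return List::create(
    _["pos"] = x, _["vel"] = v,
    _["s"] = IntegerVector(s_series.begin(), s_series.end()),
    _["frames"] = fr,
    _["frame_steps"] = NumericVector(frame_steps.begin(), frame_steps.end()),
    _["steps_done"] = steps_done,
    _["completed"] = completed);
}
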