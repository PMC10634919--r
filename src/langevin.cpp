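// Coarse-grained Langevin dynamics core: one bead per residue, harmonic
// bonds, Ashbaugh-Hatch short-range pair potential scaled by per-residue
// hydropathy, and Debye-Hueckel screened electrostatics. Units: kJ/mol, nm,
// amu, ps, K, elementary charges. Integrator is BAOAB with per-bead friction
// gamma_i = m_i / t_damp (so the O-step coefficient exp(-dt/t_damp) is the
// same for every bead).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

struct PairParams {
  double eps, cut_vdw, cut_elec, coul_pref, debye;
  int nonbonded; // 0 = off, 1 = on
};

static inline void min_image(double* d, const double* box, bool periodic) {
  if (!periodic) return;
  for (int k = 0; k < 3; ++k) d[k] -= box[k] * std::round(d[k] / box[k]);
}

// Ashbaugh-Hatch energy and (dE/dr)/r at squared distance r2.
// Works entirely in r^2 (no sqrt needed for the short-range branch).
static inline void ah_pair2(double r2, double sigma, double lambda, double eps,
                            double cut2, double& e, double& g_over_r) {
  e = 0.0; g_over_r = 0.0;
  if (r2 >= cut2) return;
  double sr2 = sigma * sigma / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double lj = 4.0 * eps * (sr12 - sr6);
  double dlj_r = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r2;
  double rmin2 = 1.2599210498948732 * sigma * sigma; // 2^(1/3) sigma^2
  if (r2 <= rmin2) {
    e = lj + (1.0 - lambda) * eps;
    g_over_r = dlj_r;
  } else {
    e = lambda * lj;
    g_over_r = lambda * dlj_r;
  }
}

// Debye-Hueckel energy and dE/dr
static inline void dh_pair(double r, double qq, double coul_pref, double debye,
                           double cut, double& e, double& dedr) {
  e = 0.0; dedr = 0.0;
  if (qq == 0.0 || r >= cut) return;
  double screen = std::isinf(debye) ? 1.0 : std::exp(-r / debye);
  e = coul_pref * qq / r * screen;
  dedr = -e / r - (std::isinf(debye) ? 0.0 : e / debye);
}

class NeighborList {
public:
  double rlist, skin;
  std::vector<std::pair<int,int>> pairs;
  std::vector<double> ref; // positions at last build

  NeighborList(double cutoff, double skin_) : rlist(cutoff + skin_),
                                              skin(skin_) {}

  void build(const std::vector<double>& x, int n, const double* box,
             bool periodic, const std::vector<std::vector<bool>>& excluded) {
    pairs.clear();
    double r2 = rlist * rlist;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excluded[i][j]) continue;
        double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1],
                       x[3*i+2] - x[3*j+2]};
        min_image(d, box, periodic);
        double dist2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (dist2 < r2) pairs.emplace_back(i, j);
      }
    }
    ref = x;
  }

  bool stale(const std::vector<double>& x, int n) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < 3 * n; i += 3) {
      double dx = x[i] - ref[i], dy = x[i+1] - ref[i+1],
             dz = x[i+2] - ref[i+2];
      if (dx*dx + dy*dy + dz*dz > lim2) return true;
    }
    return false;
  }
};

static double compute_forces(const std::vector<double>& x,
                             std::vector<double>& f, int n,
                             const NumericVector& sigma,
                             const NumericVector& lambda,
                             const NumericVector& charge,
                             const IntegerMatrix& bonds, double r0,
                             double kbond, const double* box, bool periodic,
                             const PairParams& pp, const NeighborList& nl) {
  std::fill(f.begin(), f.end(), 0.0);
  double epot = 0.0;
  // bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    min_image(d, box, periodic);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    epot += 0.5 * kbond * (r - r0) * (r - r0);
    double dedr = kbond * (r - r0);
    for (int k = 0; k < 3; ++k) {
      double fk = -dedr * d[k] / r;
      f[3*i + k] += fk;
      f[3*j + k] -= fk;
    }
  }
  if (pp.nonbonded == 0) return epot;
  // nonbonded via neighbor list
  double cut_vdw2 = pp.cut_vdw * pp.cut_vdw;
  double cut_elec2 = pp.cut_elec * pp.cut_elec;
  for (const auto& pr : nl.pairs) {
    int i = pr.first, j = pr.second;
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    min_image(d, box, periodic);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    double e1, g1; // g = (dE/dr)/r
    ah_pair2(r2, 0.5 * (sigma[i] + sigma[j]), 0.5 * (lambda[i] + lambda[j]),
             pp.eps, cut_vdw2, e1, g1);
    double g = g1;
    epot += e1;
    double qq = charge[i] * charge[j];
    if (qq != 0.0 && r2 < cut_elec2) {
      double r = std::sqrt(r2);
      double e2, de2;
      dh_pair(r, qq, pp.coul_pref, pp.debye, pp.cut_elec, e2, de2);
      epot += e2;
      g += de2 / r;
    }
    if (g != 0.0) {
      for (int k = 0; k < 3; ++k) {
        double fk = -g * d[k];
        f[3*i + k] += fk;
        f[3*j + k] -= fk;
      }
    }
  }
  return epot;
}

// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix coords0, NumericVector mass,
                      NumericVector charge, NumericVector lambda,
                      NumericVector sigma, IntegerMatrix bonds, double r0,
                      double kbond, NumericVector box_in, bool periodic,
                      double temperature, double dt, double t_damp,
                      int n_steps, int save_every, int seed, double eps,
                      int minimize_steps, int thermalize_steps,
                      double cut_vdw, double cut_elec, double coul_pref,
                      double debye, int nonbonded) {
  int n = coords0.nrow();
  double box[3] = {box_in[0], box_in[1], box_in[2]};
  PairParams pp{eps, cut_vdw, cut_elec, coul_pref, debye, nonbonded};

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i + k] = coords0(i, k);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(KB * temperature / mass[i]);
    for (int k = 0; k < 3; ++k) v[3*i + k] = s * gauss(rng);
  }

  // exclusions: bonded pairs skip the nonbonded terms
  std::vector<std::vector<bool>> excluded(n, std::vector<bool>(n, false));
  for (int b = 0; b < bonds.nrow(); ++b) {
    excluded[bonds(b, 0)][bonds(b, 1)] = true;
    excluded[bonds(b, 1)][bonds(b, 0)] = true;
  }

  bool any_charge = false;
  {
    int n_charged = 0;
    for (int i = 0; i < n; ++i) if (charge[i] != 0.0) ++n_charged;
    any_charge = n_charged >= 2;
  }
  double rmax = any_charge ? std::max(cut_vdw, cut_elec) : cut_vdw;
  NeighborList nl(rmax, 0.4);
  nl.build(x, n, box, periodic, excluded);

  // capped-displacement steepest descent to relax initial overlaps before
  // the dynamics start (random packing leaves beads inside each other's
  // repulsive cores)
  if (minimize_steps > 0) {
    const double dmax = 0.01; // nm per coordinate per iteration
    for (int it = 0; it < minimize_steps; ++it) {
      if (nl.stale(x, n)) nl.build(x, n, box, periodic, excluded);
      compute_forces(x, f, n, sigma, lambda, charge, bonds, r0, kbond, box,
                     periodic, pp, nl);
      double fmax = 1e-12;
      for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
      double scale = dmax / fmax;
      for (int i = 0; i < 3 * n; ++i) x[i] += scale * f[i];
    }
    nl.build(x, n, box, periodic, excluded);
  }

  double c1 = std::exp(-dt / t_damp);
  double c2 = std::sqrt(1.0 - c1 * c1);

  // thermalization: short strongly-coupled phase (1 ps damping) so the
  // production run starts at the target temperature with potential modes
  // populated; frames are not saved
  if (thermalize_steps > 0) {
    double c1t = std::exp(-dt / 1.0);
    double c2t = std::sqrt(1.0 - c1t * c1t);
    std::vector<double> ft(3 * n);
    compute_forces(x, ft, n, sigma, lambda, charge, bonds, r0, kbond, box,
                   periodic, pp, nl);
    for (int step = 0; step < thermalize_steps; ++step) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v[3*i + k] += 0.5 * dt * ft[3*i + k] / mass[i];
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      for (int i = 0; i < n; ++i) {
        double sv = std::sqrt(KB * temperature / mass[i]);
        for (int k = 0; k < 3; ++k)
          v[3*i + k] = c1t * v[3*i + k] + c2t * sv * gauss(rng);
      }
      for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
      if (pp.nonbonded != 0 && nl.stale(x, n))
        nl.build(x, n, box, periodic, excluded);
      compute_forces(x, ft, n, sigma, lambda, charge, bonds, r0, kbond, box,
                     periodic, pp, nl);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v[3*i + k] += 0.5 * dt * ft[3*i + k] / mass[i];
    }
  }

  int n_saved = n_steps / save_every;
  NumericVector out_coords(static_cast<R_xlen_t>(n_saved) * n * 3);
  NumericVector epot_log(n_saved), ekin_log(n_saved), time_log(n_saved);

  double epot = compute_forces(x, f, n, sigma, lambda, charge, bonds, r0,
                               kbond, box, periodic, pp, nl);
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i + k] += 0.5 * dt * f[3*i + k] / mass[i];
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(KB * temperature / mass[i]);
      for (int k = 0; k < 3; ++k)
        v[3*i + k] = c1 * v[3*i + k] + c2 * s * gauss(rng);
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // force update + B
    if (pp.nonbonded != 0 && nl.stale(x, n))
      nl.build(x, n, box, periodic, excluded);
    epot = compute_forces(x, f, n, sigma, lambda, charge, bonds, r0, kbond,
                          box, periodic, pp, nl);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i + k] += 0.5 * dt * f[3*i + k] / mass[i];

    if (step % save_every == 0) {
      double ekin = 0.0;
      for (int i = 0; i < n; ++i) {
        double vv = v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2];
        ekin += 0.5 * mass[i] * vv;
      }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          double val = x[3*i + k];
          if (!std::isfinite(val) || std::fabs(val) > 1e8)
            stop("numerical blow-up: non-finite coordinate at step %d "
                 "(atom %d); reduce the timestep or check the topology",
                 step, i + 1);
          out_coords[static_cast<R_xlen_t>(isave) * n * 3 + i * 3 + k] = val;
        }
      epot_log[isave] = epot;
      ekin_log[isave] = ekin;
      time_log[isave] = step * dt;
      ++isave;
    }
  }

  return List::create(_["coords"] = out_coords, _["potential"] = epot_log,
                      _["kinetic"] = ekin_log, _["time"] = time_log,
                      _["n_saved"] = n_saved);
}

// Total potential energy of one configuration (cross-check for the R-level
// pair potential; brute-force over all pairs, no neighbor list).
// [[Rcpp::export(name = ".cg_energy_cpp")]]
double cg_energy_cpp(NumericMatrix coords, NumericVector charge,
                     NumericVector lambda, NumericVector sigma,
                     IntegerMatrix bonds, double r0, double kbond,
                     NumericVector box_in, bool periodic, double eps,
                     double cut_vdw, double cut_elec, double coul_pref,
                     double debye, int nonbonded) {
  int n = coords.nrow();
  double box[3] = {box_in[0], box_in[1], box_in[2]};
  std::vector<std::vector<bool>> bonded(n, std::vector<bool>(n, false));
  double epot = 0.0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    bonded[i][j] = bonded[j][i] = true;
    double d[3] = {coords(i,0) - coords(j,0), coords(i,1) - coords(j,1),
                   coords(i,2) - coords(j,2)};
    min_image(d, box, periodic);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    epot += 0.5 * kbond * (r - r0) * (r - r0);
  }
  if (nonbonded == 0) return epot;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (bonded[i][j]) continue;
      double d[3] = {coords(i,0) - coords(j,0), coords(i,1) - coords(j,1),
                     coords(i,2) - coords(j,2)};
      min_image(d, box, periodic);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      double r = std::sqrt(r2);
      double e1, g1, e2, de2;
      ah_pair2(r2, 0.5 * (sigma[i] + sigma[j]), 0.5 * (lambda[i] + lambda[j]),
               eps, cut_vdw * cut_vdw, e1, g1);
      dh_pair(r, charge[i] * charge[j], coul_pref, debye, cut_elec, e2, de2);
      epot += e1 + e2;
    }
  return epot;
}

// Per-frame residue-residue heavy-atom contact counts. resid carries the
// actual residue numbers (used for the |i - j| bonded-neighbour exclusion),
// ridx the 1-based row/column of each atom's residue in the output matrix.
// mode: 0 = intramolecular (same chain, |resid_i - resid_j| > excl),
// 1 = intermolecular (different chains, minimum-image distances).
// [[Rcpp::export(name = ".contact_counts_cpp")]]
NumericMatrix contact_counts_cpp(NumericMatrix coords, IntegerVector resid,
                                 IntegerVector ridx, IntegerVector chain,
                                 LogicalVector heavy, double cutoff,
                                 int n_res, int mode, int excl,
                                 NumericVector box_in, bool periodic) {
  int n = coords.nrow();
  double box[3] = {box_in[0], box_in[1], box_in[2]};
  NumericMatrix out(n_res, n_res);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i) {
    if (!heavy[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!heavy[j]) continue;
      bool same_chain = chain[i] == chain[j];
      if (mode == 0) {
        if (!same_chain) continue;
        if (std::abs(resid[i] - resid[j]) <= excl) continue;
      } else {
        if (same_chain) continue;
      }
      double d[3] = {coords(i,0) - coords(j,0), coords(i,1) - coords(j,1),
                     coords(i,2) - coords(j,2)};
      min_image(d, box, periodic && mode == 1);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 < c2) {
        int ri = ridx[i] - 1, rj = ridx[j] - 1;
        out(ri, rj) += 1.0;
        if (ri != rj) out(rj, ri) += 1.0;
      }
    }
  }
  return out;
}
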