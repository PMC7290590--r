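#include <Rcpp.h>
#include <random>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reduced units: kT = 1, lengths in Angstrom, 1 MC step = 1 nominal ps.

namespace {

struct Pot {
  double center, depth, width, plateau;
};

struct Common {
  double iw_center, iw_depth, iw_width;
  double wall_deep, wall_water, wall_width;
};

inline double sigmoid(double u) { return 1.0 / (1.0 + std::exp(-u)); }

inline double u_state(double d, const Pot &p) {
  return p.plateau + (-p.depth - p.plateau) * sigmoid((d - p.center) / p.width);
}

inline double u_common(double d, const Common &c) {
  const double g = d - c.iw_center;
  return -c.iw_depth * std::exp(-g * g / (2.0 * c.iw_width * c.iw_width)) +
         std::exp((d - c.wall_deep) / c.wall_width) +
         std::exp(-(d - c.wall_water) / c.wall_width);
}

inline double u_total(double d, int s, const Pot &pn, const Pot &pp,
                      const Common &c) {
  return u_state(d, s == 1 ? pp : pn) + u_common(d, c);
}

// Self-contained RNG transforms so trajectories do not depend on the C++
// standard library's distribution implementations.
struct Rng {
  std::mt19937_64 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(const std::vector<unsigned int> &seeds) {
    std::seed_seq seq(seeds.begin(), seeds.end());
    gen.seed(seq);
  }
  double runif() {  // in (0, 1)
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rnorm() {  // Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    const double u1 = runif(), u2 = runif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

inline double wrap(double x, double L) {
  // floor-based periodic wrap (avoids fmod, whose symbol version varies
  // across glibc builds)
  return x - L * std::floor(x / L);
}

Pot as_pot(const NumericVector &v) {
  return Pot{v["well_center"], v["well_depth"], v["well_width"],
             v["water_plateau"]};
}

}  // namespace

// One replicate of the constant-pH / pH-replica-exchange Monte-Carlo sampler.
// Per step and replica: a joint lateral (periodic) + normal Gaussian move
// accepted by Metropolis against U_state(d_true) with d_true from the
// analytic deformed surface; every titration_period steps a protonation flip
// with acceptance min(1, exp(-dU) * 10^(ds*(pKa_water - pH))); every
// exchange_period steps pH swaps between ladder-adjacent replicas
// (odd/even pairs alternating) with acceptance min(1, 10^(dpH * dN)).
// Returns one row per (step, replica): replica, step, pH, prot, x, y, z.
// [[Rcpp::export]]
NumericMatrix cpp_run_replicate(int n_steps, NumericVector ladder,
                                double pka_water, NumericVector pot_neutral,
                                NumericVector pot_protonated,
                                NumericVector common_par,
                                NumericVector surface_par, NumericVector box,
                                double sd_lateral, double sd_normal,
                                int titration_period, int exchange_period,
                                bool exchange, int seed, int replicate_id) {
  const int L = ladder.size();
  const Pot pn = as_pot(pot_neutral), pp = as_pot(pot_protonated);
  const Common cm{common_par["iw_center"],  common_par["iw_depth"],
                  common_par["iw_width"],   common_par["wall_deep"],
                  common_par["wall_water"], common_par["wall_width"]};
  const double plane = surface_par["plane_offset"];
  const double amp = surface_par["amplitude"];
  const double lambda = surface_par["wavelength"];
  const double Lx = box[0], Ly = box[1];
  const double two_pi = 2.0 * M_PI;

  auto surf = [&](double x, double y) {
    return plane + amp * std::sin(two_pi * x / lambda) *
                       std::sin(two_pi * y / lambda);
  };

  Rng rng({static_cast<unsigned int>(seed),
           static_cast<unsigned int>(replicate_id), 0x6d656d74u});

  std::vector<double> x(L), y(L), z(L);
  std::vector<int> s(L);
  // perm[k] = replica currently holding ladder rung k; rung[r] its inverse
  std::vector<int> perm(L), rung(L);
  for (int k = 0; k < L; ++k) { perm[k] = k; rung[k] = k; }

  const double d0 = 3.0;  // start at the water/membrane interface
  for (int r = 0; r < L; ++r) {
    x[r] = rng.runif() * Lx;
    y[r] = rng.runif() * Ly;
    z[r] = surf(x[r], y[r]) - d0;
    const double dtrue = d0;
    // shared terms cancel exactly in the two-state energy difference
    const double pka = pka_water +
        (u_state(dtrue, pn) - u_state(dtrue, pp)) / std::log(10.0);
    const double p_prot = 1.0 / (1.0 + std::pow(10.0, ladder[r] - pka));
    s[r] = rng.runif() < p_prot ? 1 : 0;
  }

  NumericMatrix out(static_cast<R_xlen_t>(n_steps) * L, 7);
  long exchange_round = 0;
  R_xlen_t row = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < L; ++r) {
      const double nx = wrap(x[r] + sd_lateral * rng.rnorm(), Lx);
      const double ny = wrap(y[r] + sd_lateral * rng.rnorm(), Ly);
      const double nz = z[r] + sd_normal * rng.rnorm();
      const double d_old = surf(x[r], y[r]) - z[r];
      const double d_new = surf(nx, ny) - nz;
      const double du = u_total(d_new, s[r], pn, pp, cm) -
                        u_total(d_old, s[r], pn, pp, cm);
      if (du <= 0 || rng.runif() < std::exp(-du)) {
        x[r] = nx; y[r] = ny; z[r] = nz;
      }
    }

    if (step % titration_period == 0) {
      for (int r = 0; r < L; ++r) {
        const double d = surf(x[r], y[r]) - z[r];
        const int snew = 1 - s[r];
        const double du = u_state(d, snew == 1 ? pp : pn) -
                          u_state(d, s[r] == 1 ? pp : pn);
        const double ds = snew - s[r];
        const double pH = ladder[rung[r]];
        const double acc =
            std::exp(-du) * std::pow(10.0, ds * (pka_water - pH));
        if (rng.runif() < acc) s[r] = snew;
      }
    }

    if (exchange && L >= 2 && step % exchange_period == 0) {
      ++exchange_round;
      const int start = (exchange_round % 2 == 1) ? 0 : 1;
      for (int k = start; k + 1 < L; k += 2) {
        const int i = perm[k], j = perm[k + 1];
        const double dpH = ladder[k] - ladder[k + 1];
        const double dN = s[i] - s[j];
        const double acc = std::pow(10.0, dpH * dN);
        if (acc >= 1.0 || rng.runif() < acc) {
          std::swap(perm[k], perm[k + 1]);
          rung[i] = k + 1;
          rung[j] = k;
        }
      }
    }

    for (int r = 0; r < L; ++r) {
      out(row, 0) = r + 1;
      out(row, 1) = step;
      out(row, 2) = ladder[rung[r]];
      out(row, 3) = s[r];
      out(row, 4) = x[r];
      out(row, 5) = y[r];
      out(row, 6) = z[r];
      ++row;
    }
  }
  colnames(out) = CharacterVector::create("replica_id", "step", "pH",
                                          "prot_state", "group_x", "group_y",
                                          "group_z");
  return out;
}

// Local phosphate reference plane per frame.  Lateral distances use the
// minimum-image convention in x/y.  If at least min_atoms atoms lie within
// `radius`, ref_z is the mean z of all of them; otherwise the min_atoms
// laterally closest atoms are used (ties broken by input order, i.e. by
// atom_id when atoms are supplied in atom_id order) and the fallback flag is
// set.  Returns columns: ref_z, n_ref_atoms, fallback_used.
// [[Rcpp::export]]
NumericMatrix cpp_local_reference(NumericVector gx, NumericVector gy,
                                  NumericVector ax, NumericVector ay,
                                  NumericVector az, double box_x, double box_y,
                                  double radius, int min_atoms) {
  const R_xlen_t n = gx.size();
  const R_xlen_t m = ax.size();
  if (m < min_atoms)
    stop("leaflet has fewer phosphate-group atoms (%d) than min_atoms (%d)",
         static_cast<int>(m), min_atoms);
  const double r2 = radius * radius;
  NumericMatrix out(n, 3);
  std::vector<double> d2(m);
  std::vector<std::pair<double, int>> pairs;

  for (R_xlen_t i = 0; i < n; ++i) {
    int count = 0;
    double zsum = 0.0;
    for (R_xlen_t a = 0; a < m; ++a) {
      double dx = std::fabs(gx[i] - ax[a]);
      double dy = std::fabs(gy[i] - ay[a]);
      dx = std::min(dx, box_x - dx);
      dy = std::min(dy, box_y - dy);
      d2[a] = dx * dx + dy * dy;
      if (d2[a] <= r2) { ++count; zsum += az[a]; }
    }
    if (count >= min_atoms) {
      out(i, 0) = zsum / count;
      out(i, 1) = count;
      out(i, 2) = 0;
    } else {
      pairs.clear();
      pairs.reserve(m);
      for (R_xlen_t a = 0; a < m; ++a)
        pairs.emplace_back(d2[a], static_cast<int>(a));
      std::partial_sort(pairs.begin(), pairs.begin() + min_atoms, pairs.end());
      double zs = 0.0;
      for (int k = 0; k < min_atoms; ++k) zs += az[pairs[k].second];
      out(i, 0) = zs / min_atoms;
      out(i, 1) = min_atoms;
      out(i, 2) = 1;
    }
  }
  colnames(out) = CharacterVector::create("ref_z", "n_ref_atoms",
                                          "fallback_used");
  return out;
}
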