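#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Langevin dynamics for a bead-spring chromatin model, in reduced units
// (kT = 1, m = 1, length scaled by the smallest bead diameter). Forces:
// harmonic bonds (consecutive beads and loop bonds), purely repulsive WCA
// between all bead pairs except B-B, truncated-shifted Lennard-Jones with
// well depth eps_BB between B-B pairs, and a one-sided harmonic wall at the
// nuclear radius. BAOAB splitting, one force evaluation per step.

// fast thermostat noise: splitmix64 + polar Box-Muller, seeded from R's
// RNG stream so trajectories stay reproducible under set.seed()
struct NoiseRNG {
  uint64_t s;
  double spare;
  bool has_spare = false;
  explicit NoiseRNG(uint64_t seed) : s(seed), spare(0) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

struct CellGrid {
  double lo[3], cell;
  int n[3];
  std::vector<int> head, next;
  void build(const std::vector<double> &x, int N, double cell_size) {
    double hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = 1e300; hi[k] = -1e300; }
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], x[3 * i + k]);
        hi[k] = std::max(hi[k], x[3 * i + k]);
      }
    cell = cell_size;
    // keep the bin count O(N): rebuilding the grid every step must not
    // dominate for sparse systems
    int max_dim = std::max(4, (int)std::cbrt(8.0 * N) + 1);
    for (int k = 0; k < 3; ++k) {
      n[k] = std::max(1, (int)((hi[k] - lo[k]) / cell) + 1);
      n[k] = std::min(n[k], std::min(64, max_dim));
    }
    for (int k = 0; k < 3; ++k)
      cell = std::max(cell, (hi[k] - lo[k] + 1e-9) / n[k]);
    head.assign((size_t)n[0] * n[1] * n[2], -1);
    next.assign(N, -1);
    for (int i = 0; i < N; ++i) {
      size_t c = idx(&x[3 * i]);
      next[i] = head[c];
      head[c] = i;
    }
  }
  int clampi(double v, int k) const {
    int c = (int)std::floor((v - lo[k]) / cell);
    return std::min(std::max(c, 0), n[k] - 1);
  }
  size_t idx(const double *p) const {
    return ((size_t)clampi(p[0], 0) * n[1] + clampi(p[1], 1)) * n[2] +
           clampi(p[2], 2);
  }
};

// [[Rcpp::export]]
NumericMatrix run_dynamics_cpp(NumericMatrix pos, NumericVector diam,
                               IntegerVector labels, IntegerMatrix bonds,
                               NumericVector bond_r0, double radius,
                               int n_iter, double dt, double friction,
                               double eps_bb, double lj_cut_factor,
                               double bond_k_factor) {
  int N = pos.nrow();
  int E = bonds.nrow();
  if (n_iter == 0) return pos;

  // reduced length unit = smallest bead diameter
  double sigma_ref = R_PosInf;
  for (int i = 0; i < N; ++i) sigma_ref = std::min(sigma_ref, diam[i]);
  if (!R_FINITE(sigma_ref) || sigma_ref <= 0) stop("invalid bead diameters");

  std::vector<double> x(3 * N), v(3 * N), f(3 * N), sig(N);
  for (int i = 0; i < N; ++i) {
    sig[i] = diam[i] / sigma_ref;
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k) / sigma_ref;
  }
  double R = radius / sigma_ref;
  double sig_max = 0;
  for (int i = 0; i < N; ++i) sig_max = std::max(sig_max, sig[i]);
  double cut_max = lj_cut_factor * sig_max;
  std::vector<double> r0(E);
  std::vector<double> kb(E);
  for (int e = 0; e < E; ++e) {
    r0[e] = bond_r0[e] / sigma_ref;
    kb[e] = bond_k_factor / (r0[e] * r0[e]);
  }
  double k_wall = bond_k_factor;

  uint64_t seed = (uint64_t)std::floor(R::unif_rand() * 4294967296.0) ^
                  ((uint64_t)std::floor(R::unif_rand() * 4294967296.0) << 32);
  NoiseRNG rng(seed);
  // Maxwell-Boltzmann start velocities
  for (int i = 0; i < 3 * N; ++i) v[i] = rng.norm();

  CellGrid grid;
  const double wca_pref = std::pow(2.0, 1.0 / 6.0);

  auto forces = [&]() {
    std::fill(f.begin(), f.end(), 0.0);
    // bonds
    for (int e = 0; e < E; ++e) {
      int i = bonds(e, 0), j = bonds(e, 1);
      double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
             dz = x[3 * j + 2] - x[3 * i + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double fmag = kb[e] * (r - r0[e]) / r;
      f[3 * i] += fmag * dx; f[3 * i + 1] += fmag * dy; f[3 * i + 2] += fmag * dz;
      f[3 * j] -= fmag * dx; f[3 * j + 1] -= fmag * dy; f[3 * j + 2] -= fmag * dz;
    }
    // non-bonded via cell list
    grid.build(x, N, cut_max);
    for (int i = 0; i < N; ++i) {
      int c0 = grid.clampi(x[3 * i], 0), c1 = grid.clampi(x[3 * i + 1], 1),
          c2 = grid.clampi(x[3 * i + 2], 2);
      for (int a = std::max(0, c0 - 1); a <= std::min(grid.n[0] - 1, c0 + 1); ++a)
        for (int b = std::max(0, c1 - 1); b <= std::min(grid.n[1] - 1, c1 + 1); ++b)
          for (int c = std::max(0, c2 - 1); c <= std::min(grid.n[2] - 1, c2 + 1); ++c) {
            int j = grid.head[((size_t)a * grid.n[1] + b) * grid.n[2] + c];
            for (; j >= 0; j = grid.next[j]) {
              if (j <= i) continue;
              double dx = x[3 * j] - x[3 * i],
                     dy = x[3 * j + 1] - x[3 * i + 1],
                     dz = x[3 * j + 2] - x[3 * i + 2];
              double r2 = dx * dx + dy * dy + dz * dz;
              double s = 0.5 * (sig[i] + sig[j]);
              bool bb = labels[i] == 1 && labels[j] == 1 && eps_bb > 0;
              double cut = bb ? lj_cut_factor * s : wca_pref * s;
              if (r2 >= cut * cut || r2 < 1e-12) continue;
              double inv2 = s * s / r2;
              double inv6 = inv2 * inv2 * inv2;
              double eps = bb ? eps_bb : 1.0;
              // F/r for LJ: 24 eps (2 (s/r)^12 - (s/r)^6) / r^2
              double fr = 24.0 * eps * (2.0 * inv6 * inv6 - inv6) / r2;
              // cap the pair force so overlapping initial configurations
              // push apart smoothly instead of blowing up
              double r1 = std::sqrt(r2);
              if (std::fabs(fr) * r1 > 1e3) fr = (fr > 0 ? 1e3 : -1e3) / r1;
              f[3 * i] -= fr * dx; f[3 * i + 1] -= fr * dy; f[3 * i + 2] -= fr * dz;
              f[3 * j] += fr * dx; f[3 * j + 1] += fr * dy; f[3 * j + 2] += fr * dz;
            }
          }
    }
    // spherical confinement (one-sided harmonic wall on bead centers)
    if (R_FINITE(R)) {
      for (int i = 0; i < N; ++i) {
        double r = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                             x[3 * i + 2] * x[3 * i + 2]);
        if (r > R && r > 1e-12) {
          double fmag = -k_wall * (r - R) / r;
          f[3 * i] += fmag * x[3 * i];
          f[3 * i + 1] += fmag * x[3 * i + 1];
          f[3 * i + 2] += fmag * x[3 * i + 2];
        }
      }
    }
  };

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  forces();
  double blow = R_FINITE(R) ? 10.0 * R : 1e6;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < 3 * N; ++i) {
      v[i] += 0.5 * dt * f[i];
      x[i] += 0.5 * dt * v[i];
    }
    for (int i = 0; i < 3 * N; ++i) {
      v[i] = c1 * v[i] + c2 * rng.norm();
      x[i] += 0.5 * dt * v[i];
    }
    forces();
    for (int i = 0; i < 3 * N; ++i) v[i] += 0.5 * dt * f[i];
    if ((it & 1023) == 0) {
      for (int i = 0; i < 3 * N; ++i)
        if (std::fabs(x[i]) > blow)
          stop("numerical blow-up: bead position exceeds 10x nuclear radius");
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k] * sigma_ref;
  return out;
}

// all unordered bead pairs with center distance <= cutoff, via spatial grid
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericMatrix pos, double cutoff) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  CellGrid grid;
  grid.build(x, N, cutoff);
  std::vector<std::pair<int, int>> pairs;
  double c2cut = cutoff * cutoff;
  for (int i = 0; i < N; ++i) {
    int c0 = grid.clampi(x[3 * i], 0), c1 = grid.clampi(x[3 * i + 1], 1),
        c2 = grid.clampi(x[3 * i + 2], 2);
    for (int a = std::max(0, c0 - 1); a <= std::min(grid.n[0] - 1, c0 + 1); ++a)
      for (int b = std::max(0, c1 - 1); b <= std::min(grid.n[1] - 1, c1 + 1); ++b)
        for (int c = std::max(0, c2 - 1); c <= std::min(grid.n[2] - 1, c2 + 1); ++c) {
          int j = grid.head[((size_t)a * grid.n[1] + b) * grid.n[2] + c];
          for (; j >= 0; j = grid.next[j]) {
            if (j <= i) continue;
            double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
                   dz = x[3 * j + 2] - x[3 * i + 2];
            if (dx * dx + dy * dy + dz * dz <= c2cut)
              pairs.push_back({i, j});
          }
        }
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first + 1;
    out(p, 1) = pairs[p].second + 1;
  }
  return out;
}
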