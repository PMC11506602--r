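#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Monte Carlo kernels.  Occupancies are 0 (empty), 1, 2 (species).  Neighbour
// tables are n x 6 integer matrices of 0-based site indices; on lattices with
// L >= 5 a site never appears in its own shells, which the R wrappers enforce.

static inline double pair_v(int a, int b, int shell, double J) {
  if (a == 0 || b == 0) return 0.0;
  if (shell == 0) return (a == b) ? -1.0 : 1.0;
  return (a == b) ? J : -J;
}

// neighbour tables flattened to site-major int arrays for the hot loop
static std::vector<int> flatten_table(const IntegerMatrix &m) {
  const int n = m.nrow(), k = m.ncol();
  std::vector<int> out((size_t)n * k);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < k; ++d) out[(size_t)i * k + d] = m(i, d);
  return out;
}

static double total_energy_occ(const std::vector<int8_t> &occ,
                               const std::vector<int> &nn, const std::vector<int> &th,
                               double J) {
  const int n = occ.size();
  double E = 0.0;
  for (int i = 0; i < n; ++i) {
    if (occ[i] == 0) continue;
    for (int d = 0; d < 6; ++d) {
      E += 0.5 * pair_v(occ[i], occ[nn[(size_t)i * 6 + d]], 0, J);
      E += 0.5 * pair_v(occ[i], occ[th[(size_t)i * 6 + d]], 1, J);
    }
  }
  return E;
}

// pair-energy lookup tables by (state a, state b), built once per run:
// vnn[a*3+b] for |dx| = 1, vth[a*3+b] for |dx| = 2
static inline void build_pair_tables(double J, double *vnn, double *vth) {
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      vnn[a * 3 + b] = pair_v(a, b, 0, J);
      vth[a * 3 + b] = pair_v(a, b, 1, J);
    }
}

static inline double dE_change(const std::vector<int8_t> &occ,
                               const std::vector<int> &nn, const std::vector<int> &th,
                               int site, int s_new, const double *vnn,
                               const double *vth) {
  const int s_old = occ[site];
  double dE = 0.0;
  const int *pn = &nn[(size_t)site * 6];
  const int *pt = &th[(size_t)site * 6];
  for (int d = 0; d < 6; ++d) {
    const int b1 = occ[pn[d]], b2 = occ[pt[d]];
    dE += vnn[s_new * 3 + b1] - vnn[s_old * 3 + b1];
    dE += vth[s_new * 3 + b2] - vth[s_old * 3 + b2];
  }
  return dE;
}

// Grand-canonical Metropolis with parallel tempering across a ladder of
// (mu1, mu2) states at common T*.  One sweep = one proposed state change per
// active site.  Replica exchange swaps configurations between adjacent ladder
// states with probability min(1, exp{[(mu1a-mu1b)(N1b-N1a)+(mu2a-mu2b)(N2b-N2a)]/T*}).
// [[Rcpp::export]]
List gcmc_run_cpp(IntegerMatrix occ0, IntegerMatrix nn, IntegerMatrix th,
                  double J, double Tstar,
                  NumericVector mu1, NumericVector mu2,
                  int sweeps, int equil, int sample_interval, int swap_interval,
                  double seed, IntegerVector active, int n_snapshots) {
  const int n = occ0.nrow();
  const int R = occ0.ncol();
  if (mu1.size() != R || mu2.size() != R) stop("mu ladders must match replica count");
  if (Tstar <= 0) stop("T* must be positive");
  if (equil >= sweeps) stop("equilibration must be shorter than the total run");
  const int na = active.size();
  if (na < 1) stop("no active sites");

  Xoshiro256 rng((uint64_t)seed);
  const std::vector<int> fnn = flatten_table(nn), fth = flatten_table(th);
  double vnn[9], vth[9];
  build_pair_tables(J, vnn, vth);

  std::vector<std::vector<int8_t>> occ(R, std::vector<int8_t>(n));
  std::vector<double> E(R);
  std::vector<int> N1(R, 0), N2(R, 0);
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) {
      occ[r][i] = (int8_t)occ0(i, r);
      if (occ[r][i] == 1) ++N1[r];
      else if (occ[r][i] == 2) ++N2[r];
    }
    E[r] = total_energy_occ(occ[r], fnn, fth, J);
  }

  const int n_samples = (sweeps - equil) / std::max(sample_interval, 1);
  NumericMatrix sN1(n_samples, R), sN2(n_samples, R), sE(n_samples, R);
  std::vector<int64_t> acc(R, 0), prop(R, 0);
  int64_t swap_acc = 0, swap_prop = 0;

  // snapshot sweeps, evenly spaced over the sampling window (last one = final sweep)
  std::vector<int> snap_at;
  for (int k = 1; k <= n_snapshots; ++k)
    snap_at.push_back(equil + (int)std::llround((double)k * (sweeps - equil) / n_snapshots));
  std::vector<IntegerMatrix> snaps;
  for (int r = 0; r < R; ++r) snaps.push_back(IntegerMatrix(n, std::max(n_snapshots, 0)));

  int sample_idx = 0, snap_idx = 0, swap_parity = 0;
  for (int sw = 1; sw <= sweeps; ++sw) {
    for (int r = 0; r < R; ++r) {
      std::vector<int8_t> &o = occ[r];
      const double m1 = mu1[r], m2 = mu2[r];
      for (int t = 0; t < na; ++t) {
        int site = active[rng.unif_int(na)];
        int s_old = o[site];
        // symmetric proposal: one of the other two states, uniformly
        int alt = (int)rng.unif_int(2);
        int s_new;
        if (s_old == 0) s_new = alt ? 2 : 1;
        else if (s_old == 1) s_new = alt ? 2 : 0;
        else s_new = alt ? 1 : 0;
        double dE = dE_change(o, fnn, fth, site, s_new, vnn, vth);
        int d1 = (s_new == 1) - (s_old == 1);
        int d2 = (s_new == 2) - (s_old == 2);
        double dH = dE - m1 * d1 - m2 * d2;
        ++prop[r];
        if (dH <= 0.0 || rng.unif() < std::exp(-dH / Tstar)) {
          o[site] = (int8_t)s_new;
          E[r] += dE;
          N1[r] += d1;
          N2[r] += d2;
          ++acc[r];
        }
      }
    }
    if (R > 1 && swap_interval > 0 && sw % swap_interval == 0) {
      for (int a = swap_parity; a + 1 < R; a += 2) {
        int b = a + 1;
        double lacc = ((mu1[a] - mu1[b]) * (N1[b] - N1[a]) +
                       (mu2[a] - mu2[b]) * (N2[b] - N2[a])) / Tstar;
        ++swap_prop;
        if (lacc >= 0.0 || rng.unif() < std::exp(lacc)) {
          std::swap(occ[a], occ[b]);
          std::swap(E[a], E[b]);
          std::swap(N1[a], N1[b]);
          std::swap(N2[a], N2[b]);
          ++swap_acc;
        }
      }
      swap_parity = 1 - swap_parity;
    }
    if (sw > equil && (sw - equil) % sample_interval == 0 && sample_idx < n_samples) {
      for (int r = 0; r < R; ++r) {
        sN1(sample_idx, r) = N1[r];
        sN2(sample_idx, r) = N2[r];
        sE(sample_idx, r) = E[r];
      }
      ++sample_idx;
    }
    while (snap_idx < n_snapshots && sw == snap_at[snap_idx]) {
      for (int r = 0; r < R; ++r)
        for (int i = 0; i < n; ++i) snaps[r](i, snap_idx) = occ[r][i];
      ++snap_idx;
    }
    if ((sw & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix occ_final(n, R);
  NumericVector acc_rate(R);
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) occ_final(i, r) = occ[r][i];
    acc_rate[r] = prop[r] ? (double)acc[r] / prop[r] : NA_REAL;
  }
  List snaps_out(R);
  for (int r = 0; r < R; ++r) snaps_out[r] = snaps[r];
  return List::create(_["N1"] = sN1, _["N2"] = sN2, _["E"] = sE,
                      _["occ_final"] = occ_final, _["snapshots"] = snaps_out,
                      _["acceptance"] = acc_rate,
                      _["swap_acceptance"] = swap_prop ? (double)swap_acc / swap_prop : NA_REAL);
}

// Canonical (fixed N1, N2) dynamics: a uniformly chosen particle attempts a
// hop along a uniformly chosen nearest-neighbour direction; the move is
// rejected outright if the target cell is occupied (symmetric proposal), and
// otherwise accepted with the Metropolis probability min(1, exp(-dE/T*)).
// The temperature ladder `temps` is visited stage by stage (annealing).
// [[Rcpp::export]]
List canonical_run_cpp(IntegerVector occ0, IntegerMatrix nn, IntegerMatrix th,
                       double J, NumericVector temps,
                       int sweeps_per_stage, int sample_interval, double seed) {
  const int n = occ0.size();
  const int n_stages = temps.size();
  Xoshiro256 rng((uint64_t)seed);
  const std::vector<int> fnn = flatten_table(nn), fth = flatten_table(th);
  double vnn[9], vth[9];
  build_pair_tables(J, vnn, vth);

  std::vector<int8_t> occ(n);
  std::vector<int> pos;  // particle positions
  for (int i = 0; i < n; ++i) {
    occ[i] = (int8_t)occ0[i];
    if (occ[i] != 0) pos.push_back(i);
  }
  const int N = pos.size();
  if (N < 1) stop("no particles to move");
  for (int s = 0; s < n_stages; ++s)
    if (temps[s] <= 0) stop("temperatures must be positive");

  double E = total_energy_occ(occ, fnn, fth, J);
  const int n_samples = sweeps_per_stage / std::max(sample_interval, 1);
  NumericMatrix sE(n_samples, n_stages);
  NumericVector acc_rate(n_stages);
  IntegerMatrix stage_snaps(n, n_stages);

  for (int st = 0; st < n_stages; ++st) {
    const double T = temps[st];
    int64_t acc = 0, prop = 0;
    int sample_idx = 0;
    for (int sw = 1; sw <= sweeps_per_stage; ++sw) {
      for (int t = 0; t < N; ++t) {
        int pi = rng.unif_int(N);
        int from = pos[pi];
        int to = fnn[(size_t)from * 6 + rng.unif_int(6)];
        ++prop;
        if (occ[to] != 0) continue;  // rejected outright
        int sp = occ[from];
        // dE of moving sp from `from` to `to`: remove then insert
        double dE = dE_change(occ, fnn, fth, from, 0, vnn, vth);
        occ[from] = 0;
        dE += dE_change(occ, fnn, fth, to, sp, vnn, vth);
        if (dE <= 0.0 || rng.unif() < std::exp(-dE / T)) {
          occ[to] = (int8_t)sp;
          pos[pi] = to;
          E += dE;
          ++acc;
        } else {
          occ[from] = (int8_t)sp;
        }
      }
      if (sw % sample_interval == 0 && sample_idx < n_samples)
        sE(sample_idx++, st) = E;
      if ((sw & 0x3F) == 0) Rcpp::checkUserInterrupt();
    }
    acc_rate[st] = prop ? (double)acc / prop : NA_REAL;
    for (int i = 0; i < n; ++i) stage_snaps(i, st) = occ[i];
  }

  IntegerVector occ_final(n);
  for (int i = 0; i < n; ++i) occ_final[i] = occ[i];
  return List::create(_["E"] = sE, _["stage_snapshots"] = stage_snaps,
                      _["occ_final"] = occ_final, _["acceptance"] = acc_rate);
}
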