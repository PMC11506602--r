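#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exhaustive scan over all 3^(w*h) occupancies {0,1,2} of a w x h periodic
// unit cell on the triangular lattice.  The energy per unit cell of the
// infinite tiling is E = 1/2 * sum_{site} sum_{12 displacements} V(s_i, s_j),
// which is exact for arbitrarily small cells because displacements that wrap
// onto the site itself contribute the self-image pair with weight 1/2 each
// (the pair appears under d and -d).
//
// Rather than re-scanning for every chemical potential, the scan records the
// minimal energy for each particle-number class (N1, N2) together with up to
// `keep` minimizing motifs per class; h(mu1, mu2) for any mu is then the
// lower envelope min_{N1,N2} [Emin(N1,N2) - mu1 N1 - mu2 N2] / (w*h).

static inline double pair_v(int a, int b, int shell, double J) {
  // shell 0 = nearest neighbour (|dx| = 1), shell 1 = third neighbour (|dx| = 2)
  if (a == 0 || b == 0) return 0.0;
  if (shell == 0) return (a == b) ? -1.0 : 1.0;
  return (a == b) ? J : -J;
}

// The periodic cell is a general sublattice in Hermite normal form with
// basis vectors (w, 0) and (shear, h) in axial coordinates: crossing the top
// row re-enters shifted by `shear` columns.  shear = 0 gives the plain
// rectangular w x h torus.
// [[Rcpp::export]]
List enumerate_cell_scan_cpp(int w, int h, double J, int keep = 8, int shear = 0) {
  const int n = w * h;
  if (n < 1 || n > 16) stop("unit cell must have between 1 and 16 sites (got %d)", n);

  // displacement table: 6 nn + 6 third (doubled nn vectors)
  const int dq[12] = {1, -1, 0, 0, 1, -1, 2, -2, 0, 0, 2, -2};
  const int dr[12] = {0, 0, 1, -1, -1, 1, 0, 0, 2, -2, -2, 2};

  std::vector<int> nbr(n * 12);
  for (int r = 0; r < h; ++r) {
    for (int q = 0; q < w; ++q) {
      int s = q + w * r;
      for (int d = 0; d < 12; ++d) {
        int rr_raw = r + dr[d];
        int wraps = (int)std::floor((double)rr_raw / h);
        int rr = rr_raw - wraps * h;
        int qq = ((q + dq[d] - wraps * shear) % w + w) % w;
        nbr[s * 12 + d] = qq + w * rr;
      }
    }
  }

  const int ncls = (n + 1) * (n + 1);
  std::vector<double> emin(ncls, R_PosInf);
  std::vector<int64_t> nmin(ncls, 0);                 // count of minimizers per class
  std::vector<std::vector<int8_t>> motifs(ncls);      // up to `keep` motifs, n bytes each

  std::vector<int8_t> occ(n, 0);
  double E = 0.0;
  int N1 = 0, N2 = 0;
  const double tol = 1e-9;

  // delta of E when site k changes from s_old to s_new
  auto dE_site = [&](int k, int s_old, int s_new) -> double {
    double dE = 0.0;
    for (int d = 0; d < 12; ++d) {
      int j = nbr[k * 12 + d];
      int shell = d < 6 ? 0 : 1;
      if (j == k) {
        dE += 0.5 * (pair_v(s_new, s_new, shell, J) - pair_v(s_old, s_old, shell, J));
      } else {
        dE += pair_v(s_new, occ[j], shell, J) - pair_v(s_old, occ[j], shell, J);
      }
    }
    return dE;
  };

  auto record = [&]() {
    int cls = N1 * (n + 1) + N2;
    if (E < emin[cls] - tol) {
      emin[cls] = E;
      nmin[cls] = 1;
      motifs[cls].assign(occ.begin(), occ.end());
    } else if (E < emin[cls] + tol) {
      nmin[cls]++;
      if ((int)(motifs[cls].size() / n) < keep)
        motifs[cls].insert(motifs[cls].end(), occ.begin(), occ.end());
    }
  };

  auto bump_counts = [&](int s_old, int s_new) {
    if (s_old == 1) --N1; else if (s_old == 2) --N2;
    if (s_new == 1) ++N1; else if (s_new == 2) ++N2;
  };

  record();  // all-empty state

  // base-3 odometer: on each step the lowest non-2 digit increments and all
  // digits below it reset from 2 to 0; apply energy deltas per changed site.
  int64_t total = 1;
  for (int i = 0; i < n; ++i) total *= 3;
  for (int64_t it = 1; it < total; ++it) {
    int p = 0;
    while (occ[p] == 2) {
      E += dE_site(p, 2, 0);
      bump_counts(2, 0);
      occ[p] = 0;
      ++p;
    }
    int s_old = occ[p];
    E += dE_site(p, s_old, s_old + 1);
    bump_counts(s_old, s_old + 1);
    occ[p] = (int8_t)(s_old + 1);
    record();
    if ((it & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // pack results
  NumericMatrix emin_out(n + 1, n + 1);
  NumericMatrix nmin_out(n + 1, n + 1);
  List motifs_out(ncls);
  for (int a = 0; a <= n; ++a) {
    for (int b = 0; b <= n; ++b) {
      int cls = a * (n + 1) + b;
      emin_out(a, b) = emin[cls];
      nmin_out(a, b) = (double)nmin[cls];
      if (nmin[cls] > 0) {
        int kmot = motifs[cls].size() / n;
        IntegerMatrix mm(n, kmot);
        for (int m = 0; m < kmot; ++m)
          for (int i = 0; i < n; ++i) mm(i, m) = motifs[cls][m * n + i];
        motifs_out[cls] = mm;
      }
    }
  }
  return List::create(_["w"] = w, _["h"] = h, _["J"] = J,
                      _["emin"] = emin_out, _["n_min"] = nmin_out,
                      _["motifs"] = motifs_out, _["keep"] = keep);
}
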