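// Metropolis Monte-Carlo core of the generalized cellular Potts model.
//
// The lattice arrives flattened (CSR-style adjacency with per-pair energy
// weights). Spins are 1-based cell indices on the R side and 0-based here.
// All randomness comes from R's global generator (unif_rand), so set.seed()
// on the R side makes runs bit-reproducible. Per attempt the draw order is
// fixed: candidate site, invading neighbor, then (only for uphill moves) the
// acceptance uniform.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline int rand_int(int n) {
  // uniform on {0, ..., n-1}
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Energy change for setting spin[site] <- new_spin (both 0-based).
inline double delta_E(const int *nb_off, const int *nb_id, const double *nb_w,
                      const double *site_area, const int *spin,
                      const double *cell_area, int site, int new_spin,
                      double alpha, double lam, double A0) {
  const int s_old = spin[site];
  double dsurf = 0.0;
  for (int k = nb_off[site]; k < nb_off[site + 1]; ++k) {
    const int sj = spin[nb_id[k]];
    dsurf += nb_w[k] * ((new_spin != sj) - (s_old != sj));
  }
  const double ai = site_area[site];
  const double a_old = cell_area[s_old], a_new = cell_area[new_spin];
  const double darea = (a_old - ai - A0) * (a_old - ai - A0) - (a_old - A0) * (a_old - A0) +
                       (a_new + ai - A0) * (a_new + ai - A0) - (a_new - A0) * (a_new - A0);
  return alpha * dsurf + lam * darea;
}

} // namespace

// [[Rcpp::export]]
double cpp_delta_energy(IntegerVector nb_off, IntegerVector nb_id, NumericVector nb_w,
                        NumericVector site_area, IntegerVector spin, NumericVector cell_area,
                        int site, int new_spin, double alpha, double lam, double A0) {
  std::vector<int> sp(spin.size());
  for (int i = 0; i < spin.size(); ++i) sp[i] = spin[i] - 1;
  return delta_E(nb_off.begin(), nb_id.begin(), nb_w.begin(), site_area.begin(),
                 sp.data(), cell_area.begin(), site - 1, new_spin - 1, alpha, lam, A0);
}

// [[Rcpp::export]]
List cpp_cpm_sweeps(IntegerVector nb_off, IntegerVector nb_id, NumericVector nb_w,
                    NumericVector site_area, IntegerVector spin, NumericVector cell_area,
                    double alpha, double lam, double A0, double kT, int n_sweeps) {
  const int ns = spin.size();
  std::vector<int> sp(ns);
  for (int i = 0; i < ns; ++i) sp[i] = spin[i] - 1;
  std::vector<double> ca(cell_area.begin(), cell_area.end());

  const int *off = nb_off.begin();
  const int *ids = nb_id.begin();
  const double *w = nb_w.begin();
  const double *ar = site_area.begin();

  IntegerVector accepted(n_sweeps);
  GetRNGstate();
  for (int sw = 0; sw < n_sweeps; ++sw) {
    int acc = 0;
    for (int a = 0; a < ns; ++a) {
      const int i = rand_int(ns);
      const int deg = off[i + 1] - off[i];
      const int j = ids[off[i] + rand_int(deg)];
      const int s_new = sp[j];
      if (s_new == sp[i]) continue; // same-spin pick consumes the attempt
      const double dE = delta_E(off, ids, w, ar, sp.data(), ca.data(), i, s_new,
                                alpha, lam, A0);
      bool ok = (dE <= 0.0) || (unif_rand() < std::exp(-dE / kT));
      if (ok) {
        ca[sp[i]] -= ar[i];
        ca[s_new] += ar[i];
        sp[i] = s_new;
        ++acc;
      }
    }
    accepted[sw] = acc;
  }
  PutRNGstate();

  IntegerVector spin_out(ns);
  for (int i = 0; i < ns; ++i) spin_out[i] = sp[i] + 1;
  return List::create(_["spin"] = spin_out,
                      _["cell_area"] = NumericVector(ca.begin(), ca.end()),
                      _["accepted"] = accepted);
}

// One attempt, optionally without committing the move; used to inspect the
// proposal/acceptance machinery directly.
// [[Rcpp::export]]
List cpp_cpm_attempt(IntegerVector nb_off, IntegerVector nb_id, NumericVector nb_w,
                     NumericVector site_area, IntegerVector spin, NumericVector cell_area,
                     double alpha, double lam, double A0, double kT, bool commit) {
  const int ns = spin.size();
  std::vector<int> sp(ns);
  for (int i = 0; i < ns; ++i) sp[i] = spin[i] - 1;
  std::vector<double> ca(cell_area.begin(), cell_area.end());

  GetRNGstate();
  const int i = rand_int(ns);
  const int deg = nb_off[i + 1] - nb_off[i];
  const int j = nb_id[nb_off[i] + rand_int(deg)];
  const int s_new = sp[j];
  bool same = (s_new == sp[i]);
  double dE = NA_REAL;
  bool ok = false;
  if (!same) {
    dE = delta_E(nb_off.begin(), nb_id.begin(), nb_w.begin(), site_area.begin(),
                 sp.data(), ca.data(), i, s_new, alpha, lam, A0);
    ok = (dE <= 0.0) || (unif_rand() < std::exp(-dE / kT));
    if (ok && commit) {
      ca[sp[i]] -= site_area[i];
      ca[s_new] += site_area[i];
      sp[i] = s_new;
    }
  }
  PutRNGstate();

  IntegerVector spin_out(ns);
  for (int k = 0; k < ns; ++k) spin_out[k] = sp[k] + 1;
  return List::create(_["site"] = i + 1, _["invader"] = j + 1, _["same_spin"] = same,
                      _["delta_e"] = dE, _["accepted"] = ok, _["spin"] = spin_out,
                      _["cell_area"] = NumericVector(ca.begin(), ca.end()));
}
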