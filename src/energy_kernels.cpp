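// Pairwise kernels for energy evaluation and clash detection: flat double
// loops over atom pairs with the same-residue and peptide-bond 1-2/1-3
// exclusions. These mirror the R reference implementations (pair_kernel /
// clash_count), which remain in the package and are cross-checked in the
// tests.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// exclusion of a bonded pair across the peptide bond; lo/hi are the
// backbone codes (1 N, 2 CA, 3 C, 4 O, 0 side chain) of the atom in the
// earlier and later residue respectively
static inline bool excl_pep(int lo, int hi) {
  return (lo == 3 && hi == 1) || (lo == 3 && hi == 2) ||
         (lo == 2 && hi == 1) || (lo == 4 && hi == 1);
}

static inline bool excluded(int res_i, int bb_i, int res_j, int bb_j) {
  if (res_i == res_j) return true;
  if (res_j == res_i + 1) return excl_pep(bb_i, bb_j);
  if (res_j == res_i - 1) return excl_pep(bb_j, bb_i);
  return false;
}

// total pair energy of A x B (and optionally unordered pairs within A)
// under the binned table E with dims (20, 20, n_bins)
// [[Rcpp::export(name = ".pair_energy_cpp")]]
double pair_energy_cpp(NumericMatrix Axyz, IntegerVector Atype,
                       IntegerVector Ares, IntegerVector Abb,
                       NumericMatrix Bxyz, IntegerVector Btype,
                       IntegerVector Bres, IntegerVector Bbb,
                       NumericVector E, double r_lo, double r_hi, double w,
                       int n_bins, bool within_A) {
  int nA = Axyz.nrow(), nB = Bxyz.nrow();
  double r_hi2 = r_hi * r_hi;
  double total = 0.0;
  for (int i = 0; i < nA; i++) {
    double xi = Axyz(i, 0), yi = Axyz(i, 1), zi = Axyz(i, 2);
    for (int j = 0; j < nB; j++) {
      double dx = Bxyz(j, 0) - xi, dy = Bxyz(j, 1) - yi, dz = Bxyz(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= r_hi2) continue;
      if (excluded(Ares[i], Abb[i], Bres[j], Bbb[j])) continue;
      double d = std::sqrt(d2);
      int bin = (d < r_lo) ? 0 : 1 + (int)std::floor((d - r_lo) / w);
      if (bin >= n_bins) bin = n_bins - 1;
      int t1 = Atype[i] < Btype[j] ? Atype[i] : Btype[j];
      int t2 = Atype[i] < Btype[j] ? Btype[j] : Atype[i];
      total += E[(t1 - 1) + 20 * (t2 - 1) + 400 * bin];
    }
    if (within_A) {
      for (int j = i + 1; j < nA; j++) {
        double dx = Axyz(j, 0) - xi, dy = Axyz(j, 1) - yi,
               dz = Axyz(j, 2) - zi;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= r_hi2) continue;
        if (excluded(Ares[i], Abb[i], Ares[j], Abb[j])) continue;
        double d = std::sqrt(d2);
        int bin = (d < r_lo) ? 0 : 1 + (int)std::floor((d - r_lo) / w);
        if (bin >= n_bins) bin = n_bins - 1;
        int t1 = Atype[i] < Atype[j] ? Atype[i] : Atype[j];
        int t2 = Atype[i] < Atype[j] ? Atype[j] : Atype[i];
        total += E[(t1 - 1) + 20 * (t2 - 1) + 400 * bin];
      }
    }
  }
  return total;
}

// count of clashing pairs (distance below ratio * (rad_i + rad_j)) among
// A x B and optionally within A, with the same exclusions; early_exit
// stops at the first clash (used as a boolean test)
// [[Rcpp::export(name = ".clash_count_cpp")]]
int clash_count_cpp(NumericMatrix Axyz, NumericVector Arad,
                    IntegerVector Ares, IntegerVector Abb,
                    NumericMatrix Bxyz, NumericVector Brad,
                    IntegerVector Bres, IntegerVector Bbb, double ratio,
                    bool within_A, bool early_exit) {
  int nA = Axyz.nrow(), nB = Bxyz.nrow();
  int count = 0;
  for (int i = 0; i < nA; i++) {
    double xi = Axyz(i, 0), yi = Axyz(i, 1), zi = Axyz(i, 2);
    for (int j = 0; j < nB; j++) {
      double lim = ratio * (Arad[i] + Brad[j]);
      double dx = Bxyz(j, 0) - xi, dy = Bxyz(j, 1) - yi, dz = Bxyz(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= lim * lim) continue;
      if (excluded(Ares[i], Abb[i], Bres[j], Bbb[j])) continue;
      count++;
      if (early_exit) return count;
    }
    if (within_A) {
      for (int j = i + 1; j < nA; j++) {
        double lim = ratio * (Arad[i] + Arad[j]);
        double dx = Axyz(j, 0) - xi, dy = Axyz(j, 1) - yi,
               dz = Axyz(j, 2) - zi;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= lim * lim) continue;
        if (excluded(Ares[i], Abb[i], Ares[j], Abb[j])) continue;
        count++;
        if (early_exit) return count;
      }
    }
  }
  return count;
}
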