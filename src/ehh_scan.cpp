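#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Genome-wide XP-EHH scan core.
//
// For each core site, haplotype identity groups are extended site by site in
// each direction on the POOLED two-population sample; the pooled EHH decides
// where extension stops (cutoff / max_gap / chromosome end), so the
// per-population EHH curves are integrated over a shared support.  Returns
// the trapezoid-integrated iES per population (columns: ref, test).
//
// hap: 0/1 matrix, rows = haplotypes (ref rows then test rows),
//      columns ordered by position.  is_test marks test-population rows.

static inline double pairs2(int k) { return 0.5 * k * (k - 1); }

// [[Rcpp::export]]
NumericMatrix xpehh_scan_cpp(IntegerMatrix hap, NumericVector pos,
                             LogicalVector is_test, double cutoff,
                             double max_gap) {
  const int n = hap.nrow(), S = hap.ncol();
  int nt = 0;
  for (int i = 0; i < n; ++i) if (is_test[i]) ++nt;
  const int nr = n - nt;
  const double pr_pool = pairs2(n), pr_ref = pairs2(nr), pr_test = pairs2(nt);

  NumericMatrix out(S, 2);
  std::vector<int> group(n), newgroup(n), remap;
  std::vector<int> cnt_all, cnt_ref, cnt_test;

  for (int c = 0; c < S; ++c) {
    double ies_ref = 0.0, ies_test = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      std::fill(group.begin(), group.end(), 0);
      int ngroups = 1;
      double e_ref_prev = 1.0, e_test_prev = 1.0, d_prev = 0.0;
      int prev = c;
      for (int j = c + dir; j >= 0 && j < S; j += dir) {
        if (std::abs(pos[j] - pos[prev]) > max_gap) break;
        // refine groups by the allele at j
        remap.assign(2 * ngroups, -1);
        int next_id = 0;
        for (int i = 0; i < n; ++i) {
          int key = 2 * group[i] + hap(i, j);
          if (remap[key] < 0) remap[key] = next_id++;
          newgroup[i] = remap[key];
        }
        std::swap(group, newgroup);
        ngroups = next_id;
        cnt_all.assign(ngroups, 0);
        cnt_ref.assign(ngroups, 0);
        cnt_test.assign(ngroups, 0);
        for (int i = 0; i < n; ++i) {
          ++cnt_all[group[i]];
          if (is_test[i]) ++cnt_test[group[i]]; else ++cnt_ref[group[i]];
        }
        double s_all = 0.0, s_ref = 0.0, s_test = 0.0;
        for (int g = 0; g < ngroups; ++g) {
          s_all += pairs2(cnt_all[g]);
          s_ref += pairs2(cnt_ref[g]);
          s_test += pairs2(cnt_test[g]);
        }
        const double e_pool = s_all / pr_pool;
        const double e_ref = s_ref / pr_ref;
        const double e_test = s_test / pr_test;
        const double d = std::abs(pos[j] - pos[c]);
        ies_ref += (d - d_prev) * 0.5 * (e_ref_prev + e_ref);
        ies_test += (d - d_prev) * 0.5 * (e_test_prev + e_test);
        d_prev = d;
        e_ref_prev = e_ref;
        e_test_prev = e_test;
        if (e_pool < cutoff) break;
        prev = j;
      }
    }
    out(c, 0) = ies_ref;
    out(c, 1) = ies_test;
  }
  return out;
}
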