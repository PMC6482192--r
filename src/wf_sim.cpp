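#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher simulator for one chromosome.
//
// Diploid individuals are haplotype pairs; mating is random with selfing
// allowed.  Mutations follow an infinite-sites model on continuous
// positions in (0, L); recombination is Poisson crossovers per meiosis.
// All randomness comes from R's RNG, so set.seed() gives bit-identical
// output across runs and platforms.

struct Pop {
  int N;                                // diploid count
  std::vector<std::vector<char>> haps;  // 2N rows
  std::vector<double> pos;              // per-column positions (append order)
};

static int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// k distinct indices from 0..n-1 (partial Fisher-Yates)
static std::vector<int> sample_distinct(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) std::swap(idx[i], idx[i + runif_int(n - i)]);
  idx.resize(k);
  return idx;
}

static void gamete(const Pop& p, int parent, double rec, double L,
                   std::vector<char>& out) {
  const std::vector<char>& h0 = p.haps[2 * parent];
  const std::vector<char>& h1 = p.haps[2 * parent + 1];
  int which = unif_rand() < 0.5 ? 1 : 0;
  int ncx = (int)R::rpois(rec * L);
  if (ncx == 0) {
    out.assign(which ? h1.begin() : h0.begin(),
               which ? h1.end() : h0.end());
    return;
  }
  double bp[8];
  std::vector<double> bp_big;
  double* b = bp;
  if (ncx > 8) {
    bp_big.resize(ncx);
    b = bp_big.data();
  }
  for (int i = 0; i < ncx; ++i) b[i] = unif_rand() * L;
  std::sort(b, b + ncx);
  const size_t S = p.pos.size();
  out.resize(S);
  const double* pp = p.pos.data();
  for (size_t j = 0; j < S; ++j) {
    int k = which;
    for (int i = 0; i < ncx; ++i) k += (pp[j] >= b[i]);
    out[j] = (k & 1) ? h1[j] : h0[j];
  }
}

// one generation: selection (genic, fitness 1 / 1+s/2 / 1+s per sweep
// locus, multiplicative across loci), reproduction, then mutation
static void next_generation(Pop& p, std::vector<std::vector<char>>& scratch,
                            int Nnext, const std::vector<int>& sweep_cols,
                            const std::vector<double>& sweep_s,
                            double rec, double L, double mu) {
  int N = p.N;
  std::vector<double> cum;
  bool sel = !sweep_cols.empty();
  if (sel) {
    cum.resize(N);
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0;
      for (size_t k = 0; k < sweep_cols.size(); ++k) {
        int c = sweep_cols[k];
        int dose = p.haps[2 * i][c] + p.haps[2 * i + 1][c];
        if (dose == 1) w *= 1.0 + sweep_s[k] / 2.0;
        else if (dose == 2) w *= 1.0 + sweep_s[k];
      }
      tot += w;
      cum[i] = tot;
    }
  }
  scratch.resize(2 * Nnext);
  for (int i = 0; i < 2 * Nnext; ++i) {
    int parent;
    if (sel) {
      double u = unif_rand() * cum[N - 1];
      parent = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (parent >= N) parent = N - 1;
    } else {
      parent = runif_int(N);
    }
    gamete(p, parent, rec, L, scratch[i]);
  }
  p.haps.swap(scratch);
  p.N = Nnext;
  int nm = (int)R::rpois(2.0 * Nnext * mu * L);
  if (nm > 0) {
    size_t S0 = p.pos.size();
    for (size_t r = 0; r < p.haps.size(); ++r) {
      p.haps[r].insert(p.haps[r].end(), nm, 0);
    }
    for (int m = 0; m < nm; ++m) {
      p.pos.push_back(unif_rand() * L);
      p.haps[runif_int(2 * Nnext)][S0 + m] = 1;
    }
  }
}

// drop lost columns (and, when drop_fixed, fixed ones); protected
// positions (sweep loci) are always kept
static void prune(Pop& p, bool drop_fixed,
                  const std::vector<double>& protect) {
  size_t S = p.pos.size();
  int n = 2 * p.N;
  std::vector<int> sum(S, 0);
  for (size_t r = 0; r < p.haps.size(); ++r) {
    const std::vector<char>& h = p.haps[r];
    for (size_t j = 0; j < S; ++j) sum[j] += h[j];
  }
  std::vector<size_t> keep;
  keep.reserve(S);
  for (size_t j = 0; j < S; ++j) {
    bool prot = std::find(protect.begin(), protect.end(), p.pos[j]) !=
                protect.end();
    if (prot || (sum[j] > 0 && (!drop_fixed || sum[j] < n))) keep.push_back(j);
  }
  if (keep.size() == S) return;
  std::vector<double> np(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) np[k] = p.pos[keep[k]];
  for (size_t r = 0; r < p.haps.size(); ++r) {
    std::vector<char> nh(keep.size());
    for (size_t k = 0; k < keep.size(); ++k) nh[k] = p.haps[r][keep[k]];
    p.haps[r].swap(nh);
  }
  p.pos.swap(np);
}

// [[Rcpp::export]]
List wf_sim_chrom_cpp(double L, int Ne, double mu, double rec, int burnin,
                      int n_wild, int n_farm, int farm_founders, int farm_Ne,
                      int gens_farm, NumericVector sweep_pos,
                      NumericVector sweep_s, int max_restarts) {
  if (Ne < 2 || farm_founders < 2) stop("population sizes must be >= 2");
  if (n_wild > Ne || n_farm > farm_Ne) {
    stop("sample sizes exceed population sizes");
  }
  const std::vector<double> no_protect;
  std::vector<double> protect(sweep_pos.begin(), sweep_pos.end());
  std::vector<std::vector<char>> scratch;

  Pop anc;
  anc.N = Ne;
  anc.haps.assign(2 * Ne, std::vector<char>());
  for (int g = 0; g < burnin; ++g) {
    next_generation(anc, scratch, Ne, std::vector<int>(),
                    std::vector<double>(), rec, L, mu);
    if (g % 3 == 2) prune(anc, true, no_protect);
  }
  prune(anc, true, no_protect);

  const int nsweep = sweep_pos.size();
  const bool null_split = (gens_farm == 0 && nsweep == 0);
  int restarts = 0;
  NumericVector sweep_freq(nsweep);

  std::vector<std::vector<char>> wild_rows, farm_rows;
  std::vector<double> wild_posv, farm_posv;

  if (null_split) {
    // one panmictic pool split randomly into disjoint samples
    std::vector<int> pick = sample_distinct(Ne, n_wild + n_farm);
    for (int i = 0; i < n_wild; ++i) {
      wild_rows.push_back(anc.haps[2 * pick[i]]);
      wild_rows.push_back(anc.haps[2 * pick[i] + 1]);
    }
    for (int i = 0; i < n_farm; ++i) {
      int s = pick[n_wild + i];
      farm_rows.push_back(anc.haps[2 * s]);
      farm_rows.push_back(anc.haps[2 * s + 1]);
    }
    wild_posv = anc.pos;
    farm_posv = anc.pos;
  } else {
    // wild lineage continues neutrally at size Ne
    Pop wild = anc;
    for (int g = 0; g < gens_farm; ++g) {
      next_generation(wild, scratch, Ne, std::vector<int>(),
                      std::vector<double>(), rec, L, mu);
      if (g % 10 == 9) prune(wild, false, no_protect);  // keep fixed columns
    }

    // farm lineage: founder bottleneck, then census farm_Ne under genic
    // selection on de novo sweep alleles; restart (conditioning on
    // establishment) if any sweep allele is lost
    Pop farm;
    for (;;) {
      farm.N = farm_founders;
      farm.pos = anc.pos;
      farm.haps.clear();
      std::vector<int> f = sample_distinct(Ne, farm_founders);
      for (int i = 0; i < farm_founders; ++i) {
        farm.haps.push_back(anc.haps[2 * f[i]]);
        farm.haps.push_back(anc.haps[2 * f[i] + 1]);
      }
      std::vector<int> sweep_cols(nsweep);
      for (int k = 0; k < nsweep; ++k) {
        sweep_cols[k] = farm.pos.size();
        farm.pos.push_back(sweep_pos[k]);
        for (size_t r = 0; r < farm.haps.size(); ++r) {
          farm.haps[r].push_back(0);
        }
        farm.haps[runif_int(2 * farm_founders)].back() = 1;
      }
      std::vector<double> s(sweep_s.begin(), sweep_s.end());
      for (int g = 0; g < gens_farm; ++g) {
        next_generation(farm, scratch, farm_Ne, sweep_cols, s, rec, L, mu);
      }
      bool ok = true;
      for (int k = 0; k < nsweep; ++k) {
        int tot = 0;
        for (size_t r = 0; r < farm.haps.size(); ++r) {
          tot += farm.haps[r][sweep_cols[k]];
        }
        sweep_freq[k] = tot / (2.0 * farm.N);
        if (tot == 0) ok = false;
      }
      if (ok) break;
      if (++restarts > max_restarts) {
        stop("sweep allele lost in all restarts; increase s or founders");
      }
    }
    prune(farm, false, protect);

    std::vector<int> pw = sample_distinct(Ne, n_wild);
    for (int i = 0; i < n_wild; ++i) {
      wild_rows.push_back(wild.haps[2 * pw[i]]);
      wild_rows.push_back(wild.haps[2 * pw[i] + 1]);
    }
    std::vector<int> pf = sample_distinct(farm.N, n_farm);
    for (int i = 0; i < n_farm; ++i) {
      farm_rows.push_back(farm.haps[2 * pf[i]]);
      farm_rows.push_back(farm.haps[2 * pf[i] + 1]);
    }
    wild_posv = wild.pos;
    farm_posv = farm.pos;
  }

  // merge the two lineages' site lists (positions absent from a lineage
  // carry the ancestral 0 allele there) and drop sites monomorphic in the
  // combined sample
  std::map<double, std::pair<int, int>> site;
  for (size_t j = 0; j < wild_posv.size(); ++j) {
    site[wild_posv[j]] = std::make_pair((int)j, -1);
  }
  for (size_t j = 0; j < farm_posv.size(); ++j) {
    std::map<double, std::pair<int, int>>::iterator it =
        site.find(farm_posv[j]);
    if (it == site.end()) {
      site[farm_posv[j]] = std::make_pair(-1, (int)j);
    } else {
      it->second.second = (int)j;
    }
  }
  int nhap = 2 * (n_wild + n_farm);
  std::vector<double> keep_pos;
  std::vector<std::vector<char>> cols;
  for (std::map<double, std::pair<int, int>>::iterator it = site.begin();
       it != site.end(); ++it) {
    std::vector<char> col(nhap, 0);
    int wj = it->second.first, fj = it->second.second;
    int tot = 0;
    for (int r = 0; r < 2 * n_wild; ++r) {
      col[r] = (wj >= 0) ? wild_rows[r][wj] : 0;
      tot += col[r];
    }
    for (int r = 0; r < 2 * n_farm; ++r) {
      col[2 * n_wild + r] = (fj >= 0) ? farm_rows[r][fj] : 0;
      tot += col[2 * n_wild + r];
    }
    if (tot > 0 && tot < nhap) {
      keep_pos.push_back(it->first);
      cols.push_back(col);
    }
  }
  IntegerMatrix haps(nhap, (int)keep_pos.size());
  for (size_t j = 0; j < keep_pos.size(); ++j) {
    for (int r = 0; r < nhap; ++r) haps(r, j) = cols[j][r];
  }
  return List::create(_["pos"] = NumericVector(keep_pos.begin(),
                                               keep_pos.end()),
                      _["haps"] = haps,
                      _["sweep_freq"] = sweep_freq,
                      _["restarts"] = restarts);
}
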