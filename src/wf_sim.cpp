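// Forward Wright-Fisher simulator with recombination, infinite-sites
// mutation on a continuous chromosome, and optional genic selection at a
// single site.  Uses R's RNG throughout so set.seed() on the R side gives
// full determinism.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

typedef std::vector<double> Hap; // sorted mutation positions carried

struct Pop {
  std::vector<Hap> haps;   // 2N haplotypes
  std::vector<char> sel;   // 1 = carries the sweep allele
};

static inline int sample_weighted(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (idx >= (int)cum.size()) idx = (int)cum.size() - 1;
  return idx;
}

static inline void copy_range(const Hap& src, double lo, double hi, Hap& dst) {
  Hap::const_iterator a = std::lower_bound(src.begin(), src.end(), lo);
  Hap::const_iterator b = std::lower_bound(src.begin(), src.end(), hi);
  dst.insert(dst.end(), a, b);
}

// One gamete from diploid `dip`: recombine the two parental haplotypes and
// superimpose new mutations.
static void make_gamete(const Pop& pop, int dip, double L, double mu, double r,
                        double sweep_pos, Hap& out, char& out_sel) {
  out.clear();
  const Hap* h[2] = { &pop.haps[2 * dip], &pop.haps[2 * dip + 1] };
  char s[2] = { pop.sel[2 * dip], pop.sel[2 * dip + 1] };
  int side = (unif_rand() < 0.5) ? 0 : 1;
  int nbk = (int) R::rpois(r * L);
  out_sel = 0;
  if (nbk == 0) {
    out = *h[side];
    out_sel = s[side];
  } else {
    std::vector<double> bks((size_t)nbk);
    for (int i = 0; i < nbk; i++) bks[i] = unif_rand() * L;
    std::sort(bks.begin(), bks.end());
    double lo = 0.0;
    for (int i = 0; i <= nbk; i++) {
      double hi = (i < nbk) ? bks[i] : L;
      copy_range(*h[side], lo, hi, out);
      if (sweep_pos >= lo && sweep_pos < hi) out_sel = s[side];
      lo = hi;
      side = 1 - side;
    }
  }
  int nm = (int) R::rpois(mu * L);
  if (nm > 0) {
    size_t old = out.size();
    for (int i = 0; i < nm; i++) out.push_back(unif_rand() * L);
    std::sort(out.begin() + old, out.end());
    std::inplace_merge(out.begin(), out.begin() + old, out.end());
  }
}

static void next_generation(const Pop& src, Pop& dst, int N, double L,
                            double mu, double r, double s, double sweep_pos,
                            bool selection) {
  std::vector<double> cum;
  if (selection) {
    cum.resize((size_t)N);
    double acc = 0.0;
    for (int i = 0; i < N; i++) {
      int g = src.sel[2 * i] + src.sel[2 * i + 1];
      acc += 1.0 + s * g; // additive fitness 1, 1+s, 1+2s
      cum[i] = acc;
    }
  }
  for (int i = 0; i < N; i++) {
    for (int w = 0; w < 2; w++) {
      int par = selection ? sample_weighted(cum) : (int)(unif_rand() * N);
      if (par >= N) par = N - 1;
      make_gamete(src, par, L, mu, r, sweep_pos,
                  dst.haps[2 * i + w], dst.sel[2 * i + w]);
    }
  }
}

// Remove mutations fixed in the whole population (they are invisible to the
// sample spectrum and would otherwise accumulate without bound).
static void drop_fixed(Pop& pop) {
  int n = (int)pop.haps.size();
  int ref = 0;
  for (int i = 1; i < n; i++)
    if (pop.haps[i].size() < pop.haps[ref].size()) ref = i;
  Hap fixed;
  for (size_t k = 0; k < pop.haps[ref].size(); k++) {
    double m = pop.haps[ref][k];
    bool all = true;
    for (int i = 0; i < n && all; i++) {
      if (i == ref) continue;
      const Hap& h = pop.haps[i];
      if (!std::binary_search(h.begin(), h.end(), m)) all = false;
    }
    if (all) fixed.push_back(m);
  }
  if (fixed.empty()) return;
  for (int i = 0; i < n; i++) {
    Hap keep;
    keep.reserve(pop.haps[i].size());
    std::set_difference(pop.haps[i].begin(), pop.haps[i].end(),
                        fixed.begin(), fixed.end(), std::back_inserter(keep));
    pop.haps[i].swap(keep);
  }
}

// [[Rcpp::export]]
List wf_sim_cpp(int n_diploids, double L, double mu, double r, int N,
                double s, double sweep_pos, double target_freq,
                int burnin_gens, int max_tries, int max_sweep_gens) {
  Pop a, b;
  a.haps.resize((size_t)(2 * N));
  a.sel.assign((size_t)(2 * N), 0);
  b.haps.resize((size_t)(2 * N));
  b.sel.assign((size_t)(2 * N), 0);

  Pop* cur = &a;
  Pop* nxt = &b;
  for (int g = 0; g < burnin_gens; g++) {
    next_generation(*cur, *nxt, N, L, mu, r, 0.0, sweep_pos, false);
    std::swap(cur, nxt);
    if ((g + 1) % 64 == 0) drop_fixed(*cur);
  }
  drop_fixed(*cur);

  int tries = 0;
  bool success = (s <= 0.0);
  if (s > 0.0) {
    Pop base = *cur; // standing variation at burn-in end
    int need = (int)std::ceil(target_freq * 2.0 * N - 1e-9);
    while (tries < max_tries && !success) {
      tries++;
      *cur = base;
      int h0 = (int)(unif_rand() * 2 * N);
      if (h0 >= 2 * N) h0 = 2 * N - 1;
      std::fill(cur->sel.begin(), cur->sel.end(), 0);
      cur->sel[(size_t)h0] = 1;
      for (int g = 0; g < max_sweep_gens; g++) {
        next_generation(*cur, *nxt, N, L, mu, r, s, sweep_pos, true);
        std::swap(cur, nxt);
        int cnt = 0;
        for (int i = 0; i < 2 * N; i++) cnt += cur->sel[i];
        if (cnt == 0) break;       // lost: resample trajectory
        if (cnt >= need) { success = true; break; }
      }
    }
    if (!success) {
      return List::create(_["success"] = false, _["tries"] = tries);
    }
  }

  // sample n_diploids distinct individuals (partial Fisher-Yates)
  std::vector<int> perm((size_t)N);
  for (int i = 0; i < N; i++) perm[i] = i;
  for (int i = 0; i < n_diploids; i++) {
    int j = i + (int)(unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(perm[i], perm[j]);
  }
  int nh = 2 * n_diploids;
  std::vector<const Hap*> sh((size_t)nh);
  std::vector<char> ssel((size_t)nh);
  for (int i = 0; i < n_diploids; i++) {
    sh[2 * i] = &cur->haps[2 * perm[i]];
    sh[2 * i + 1] = &cur->haps[2 * perm[i] + 1];
    ssel[2 * i] = cur->sel[2 * perm[i]];
    ssel[2 * i + 1] = cur->sel[2 * perm[i] + 1];
  }

  // segregating sites in the sample
  Hap all;
  for (int i = 0; i < nh; i++)
    all.insert(all.end(), sh[i]->begin(), sh[i]->end());
  std::sort(all.begin(), all.end());
  Hap kept;
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) j++;
    size_t cnt = j - i;
    if (cnt > 0 && cnt < (size_t)nh) kept.push_back(all[i]);
    i = j;
  }

  int sel_cnt = 0;
  for (int k = 0; k < nh; k++) sel_cnt += ssel[k];
  bool focal_seg = (s > 0.0 && sel_cnt > 0 && sel_cnt < nh);
  double focal_key = -1.0;
  if (focal_seg) {
    kept.push_back(sweep_pos);
    std::sort(kept.begin(), kept.end());
    focal_key = sweep_pos;
  }

  int S = (int)kept.size();
  std::unordered_map<double, int> col;
  col.reserve((size_t)S * 2);
  for (int c = 0; c < S; c++) col[kept[c]] = c;

  IntegerMatrix H(nh, S);
  for (int hdx = 0; hdx < nh; hdx++) {
    const Hap& hp = *sh[hdx];
    for (size_t k = 0; k < hp.size(); k++) {
      std::unordered_map<double, int>::iterator it = col.find(hp[k]);
      if (it != col.end()) H(hdx, it->second) = 1;
    }
    if (focal_seg && ssel[hdx]) H(hdx, col[focal_key]) = 1;
  }

  // integer 1-based bp positions, strictly increasing via forward nudge
  NumericVector pos_bp(S);
  LogicalVector is_focal(S);
  double prev = 0.0;
  for (int c = 0; c < S; c++) {
    double p = std::floor(kept[c]) + 1.0;
    if (p <= prev) p = prev + 1.0;
    pos_bp[c] = p;
    prev = p;
    is_focal[c] = (focal_seg && kept[c] == focal_key);
  }

  return List::create(_["success"] = true,
                      _["haps"] = H,
                      _["pos_bp"] = pos_bp,
                      _["is_focal"] = is_focal,
                      _["sweep_count"] = sel_cnt,
                      _["n_haplotypes"] = nh,
                      _["tries"] = tries);
}
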