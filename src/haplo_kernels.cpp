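// EHH / iHS / nSL kernels.  Haplotypes are rows (0/1 coded, 1 = derived
// after polarisation on the R side), SNPs are columns, positions in bp.
//
// EHH is computed by outward partition refinement over the carrier set of
// the core allele: at each flanking SNP the carrier groups are split by the
// allele observed there, and EHH is the without-replacement probability that
// two random carriers fall in the same group.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline double homozygosity(const std::vector<int>& grp_sizes, int K) {
  if (K < 2) return 0.0;
  double num = 0.0;
  for (size_t i = 0; i < grp_sizes.size(); i++) {
    double g = (double)grp_sizes[i];
    num += g * (g - 1.0);
  }
  return num / ((double)K * (K - 1.0));
}

// Refine partition `grp` (group id per carrier) by alleles at column j.
static void refine(const IntegerMatrix& haps, const std::vector<int>& members,
                   std::vector<int>& grp, int j, int& n_groups) {
  // new id = 2*old + allele, then compact
  std::vector<int> key(members.size());
  for (size_t i = 0; i < members.size(); i++)
    key[i] = 2 * grp[i] + haps(members[i], j);
  std::vector<int> uniq(key);
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  for (size_t i = 0; i < members.size(); i++)
    grp[i] = (int)(std::lower_bound(uniq.begin(), uniq.end(), key[i]) -
                   uniq.begin());
  n_groups = (int)uniq.size();
}

static void group_sizes(const std::vector<int>& grp, int n_groups,
                        std::vector<int>& sizes) {
  sizes.assign((size_t)n_groups, 0);
  for (size_t i = 0; i < grp.size(); i++) sizes[grp[i]]++;
}

// Full EHH curve for one focal SNP / core allele; NA outside the computed
// extent.  Truncated when EHH < cutoff or when an inter-SNP gap exceeds
// max_gap (bp).
// [[Rcpp::export]]
NumericVector ehh_curve_cpp(const IntegerMatrix& haps,
                            const NumericVector& pos, int focal0, int allele,
                            double cutoff, double max_gap) {
  int S = haps.ncol();
  NumericVector out(S, NA_REAL);
  std::vector<int> members;
  for (int h = 0; h < haps.nrow(); h++)
    if (haps(h, focal0) == allele) members.push_back(h);
  int K = (int)members.size();
  if (K < 2) return out;
  out[focal0] = 1.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> grp(members.size(), 0);
    int n_groups = 1;
    double h_prev = 1.0;
    int j = focal0;
    while (true) {
      int nj = j + dir;
      if (nj < 0 || nj >= S) break;
      if (std::abs(pos[nj] - pos[j]) > max_gap) break;
      refine(haps, members, grp, nj, n_groups);
      std::vector<int> sizes;
      group_sizes(grp, n_groups, sizes);
      double h = homozygosity(sizes, K);
      out[nj] = h;
      j = nj;
      if (h < cutoff) break;
      if (h == 0.0) { // stays 0: fill outward without further refinement
        while (true) {
          int fj = j + dir;
          if (fj < 0 || fj >= S) break;
          if (std::abs(pos[fj] - pos[j]) > max_gap) break;
          out[fj] = 0.0;
          j = fj;
        }
        break;
      }
      h_prev = h;
    }
    (void)h_prev;
  }
  return out;
}

// One-sided integrated EHH (trapezoid over bp, gap-scaled) for one core
// allele.  Integration stops at the first SNP with EHH < cutoff (its
// trapezoid segment is included), at a gap > max_gap, or at the chromosome
// end.
static double ihh_side(const IntegerMatrix& haps, const NumericVector& pos,
                       int focal0, int allele, int dir, double cutoff,
                       double max_gap, double gap_scale) {
  std::vector<int> members;
  for (int h = 0; h < haps.nrow(); h++)
    if (haps(h, focal0) == allele) members.push_back(h);
  int K = (int)members.size();
  if (K < 2) return NA_REAL;
  int S = haps.ncol();
  std::vector<int> grp(members.size(), 0);
  int n_groups = 1;
  double h_prev = 1.0, area = 0.0;
  int j = focal0;
  while (true) {
    int nj = j + dir;
    if (nj < 0 || nj >= S) break;
    double gap = std::abs(pos[nj] - pos[j]);
    if (gap > max_gap) break;
    double d = (gap > gap_scale) ? gap_scale : gap; // gap penalty
    refine(haps, members, grp, nj, n_groups);
    std::vector<int> sizes;
    group_sizes(grp, n_groups, sizes);
    double h = homozygosity(sizes, K);
    area += 0.5 * (h_prev + h) * d;
    h_prev = h;
    j = nj;
    if (h < cutoff || h == 0.0) break;
  }
  return area;
}

// Mean one-sided haplotype-sharing extent in (gap-scaled) segregating-site
// units: sum over outward steps of P(random carrier pair still identical)
// times the step weight.  This equals the all-pairs mean of per-pair maximal
// shared extents.
static double nsl_side(const IntegerMatrix& haps, const NumericVector& pos,
                       int focal0, int allele, int dir, double max_gap,
                       double gap_scale) {
  std::vector<int> members;
  for (int h = 0; h < haps.nrow(); h++)
    if (haps(h, focal0) == allele) members.push_back(h);
  int K = (int)members.size();
  if (K < 2) return NA_REAL;
  int S = haps.ncol();
  std::vector<int> grp(members.size(), 0);
  int n_groups = 1;
  double total = 0.0;
  int j = focal0;
  while (true) {
    int nj = j + dir;
    if (nj < 0 || nj >= S) break;
    double gap = std::abs(pos[nj] - pos[j]);
    if (gap > max_gap) break;
    double w = (gap > gap_scale) ? gap_scale / gap : 1.0;
    refine(haps, members, grp, nj, n_groups);
    std::vector<int> sizes;
    group_sizes(grp, n_groups, sizes);
    double h = homozygosity(sizes, K);
    total += h * w;
    j = nj;
    if (h == 0.0) break;
  }
  return total;
}

// Per-SNP iHH for ancestral (allele 0) and derived (allele 1) carriers.
// Columns of the result: derived frequency, ihh_a, ihh_d, code
// (0 ok, 1 = monomorphic/failed frequency bounds, 2 = zero iHH).
// [[Rcpp::export]]
NumericMatrix ihs_scan_cpp(const IntegerMatrix& haps, const NumericVector& pos,
                           double maf_min, double cutoff, double max_gap,
                           double gap_scale) {
  int S = haps.ncol(), nh = haps.nrow();
  NumericMatrix out(S, 4);
  for (int s = 0; s < S; s++) {
    int cnt = 0;
    for (int h = 0; h < nh; h++) cnt += haps(h, s);
    double f = (double)cnt / nh;
    out(s, 0) = f;
    if (f < maf_min || f > 1.0 - maf_min) {
      out(s, 1) = NA_REAL; out(s, 2) = NA_REAL; out(s, 3) = 1;
      continue;
    }
    double ia = ihh_side(haps, pos, s, 0, -1, cutoff, max_gap, gap_scale) +
                ihh_side(haps, pos, s, 0, +1, cutoff, max_gap, gap_scale);
    double id = ihh_side(haps, pos, s, 1, -1, cutoff, max_gap, gap_scale) +
                ihh_side(haps, pos, s, 1, +1, cutoff, max_gap, gap_scale);
    out(s, 1) = ia;
    out(s, 2) = id;
    out(s, 3) = (!R_finite(ia) || !R_finite(id) || ia <= 0.0 || id <= 0.0)
                    ? 2.0 : 0.0;
  }
  return out;
}

// Per-SNP mean pairwise shared extent (SL) for ancestral / derived carriers,
// focal site counted once per pair.
// [[Rcpp::export]]
NumericMatrix nsl_scan_cpp(const IntegerMatrix& haps, const NumericVector& pos,
                           double maf_min, double max_gap, double gap_scale) {
  int S = haps.ncol(), nh = haps.nrow();
  NumericMatrix out(S, 4);
  for (int s = 0; s < S; s++) {
    int cnt = 0;
    for (int h = 0; h < nh; h++) cnt += haps(h, s);
    double f = (double)cnt / nh;
    out(s, 0) = f;
    if (f < maf_min || f > 1.0 - maf_min) {
      out(s, 1) = NA_REAL; out(s, 2) = NA_REAL; out(s, 3) = 1;
      continue;
    }
    double la = nsl_side(haps, pos, s, 0, -1, max_gap, gap_scale);
    double ra = nsl_side(haps, pos, s, 0, +1, max_gap, gap_scale);
    double ld = nsl_side(haps, pos, s, 1, -1, max_gap, gap_scale);
    double rd = nsl_side(haps, pos, s, 1, +1, max_gap, gap_scale);
    double sa = (R_finite(la) && R_finite(ra)) ? 1.0 + la + ra : NA_REAL;
    double sd = (R_finite(ld) && R_finite(rd)) ? 1.0 + ld + rd : NA_REAL;
    out(s, 1) = sa;
    out(s, 2) = sd;
    out(s, 3) = (!R_finite(sa) || !R_finite(sd) || sa <= 0.0 || sd <= 0.0)
                    ? 2.0 : 0.0;
  }
  return out;
}
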