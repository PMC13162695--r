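#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Haplotype homozygosity of prefix groups. `group` holds a partition of the
// haplotypes; refine it by the alleles at site `site` and return the updated
// number of groups. Sizes are recomputed by the caller.
static int refine(const IntegerMatrix& H, int site, std::vector<int>& group,
                  int ngroup, std::vector<int>& remap) {
  int n = group.size();
  remap.assign(2 * ngroup, -1);
  int next = 0;
  for (int i = 0; i < n; i++) {
    int key = group[i] * 2 + H(i, site);
    if (remap[key] < 0) remap[key] = next++;
    group[i] = remap[key];
  }
  return next;
}

static double homozygosity(const std::vector<int>& group, int ngroup) {
  int n = group.size();
  std::vector<int> size(ngroup, 0);
  for (int i = 0; i < n; i++) size[group[i]]++;
  double num = 0.0;
  for (int g = 0; g < ngroup; g++)
    num += (double)size[g] * (size[g] - 1) / 2.0;
  return num / ((double)n * (n - 1) / 2.0);
}

// EHH decay curve from a core site outward in one direction.
// EHH at the core itself is 1 by definition; each further site refines the
// haplotype partition. Returns EHH at each site from the core outward
// (including the core, EHH = 1, as the first element).
// [[Rcpp::export]]
NumericVector cpp_ehh_decay(IntegerMatrix H, int core, int direction) {
  int S = H.ncol();
  std::vector<int> group(H.nrow(), 0), remap;
  int ngroup = 1;
  std::vector<double> out;
  out.push_back(1.0);
  int s = core + direction;
  while (s >= 0 && s < S) {
    ngroup = refine(H, s, group, ngroup, remap);
    out.push_back(homozygosity(group, ngroup));
    s += direction;
  }
  return NumericVector(out.begin(), out.end());
}

// Integrated EHH (trapezoid over physical distance) in one direction from a
// core, truncated when EHH drops below min_ehh, when the gap between
// consecutive sites exceeds max_gap, or at the end of the chromosome.
static double ihh_one(const IntegerMatrix& H, const NumericVector& pos,
                      int core, int direction, double min_ehh,
                      double max_gap) {
  int S = H.ncol();
  std::vector<int> group(H.nrow(), 0), remap;
  int ngroup = 1;
  double ihh = 0.0, prev_ehh = 1.0, prev_pos = pos[core];
  int s = core + direction;
  while (s >= 0 && s < S) {
    double gap = std::abs(pos[s] - prev_pos);
    if (gap > max_gap) break;
    ngroup = refine(H, s, group, ngroup, remap);
    double e = homozygosity(group, ngroup);
    ihh += 0.5 * (prev_ehh + e) * gap;
    prev_ehh = e;
    prev_pos = pos[s];
    if (e < min_ehh) break;
    s += direction;
  }
  return ihh;
}

// Raw (unstandardized) XP-EHH scores ln(iHH_A / iHH_B) at every site.
// NA where either integral is zero.
// [[Rcpp::export]]
NumericVector cpp_xpehh_raw(IntegerMatrix HA, IntegerMatrix HB,
                            NumericVector pos, double min_ehh,
                            double max_gap) {
  int S = pos.size();
  NumericVector out(S);
  for (int c = 0; c < S; c++) {
    double ia = ihh_one(HA, pos, c, -1, min_ehh, max_gap) +
                ihh_one(HA, pos, c, +1, min_ehh, max_gap);
    double ib = ihh_one(HB, pos, c, -1, min_ehh, max_gap) +
                ihh_one(HB, pos, c, +1, min_ehh, max_gap);
    out[c] = (ia > 0.0 && ib > 0.0) ? std::log(ia / ib) : NA_REAL;
  }
  return out;
}
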