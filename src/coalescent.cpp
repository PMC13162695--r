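#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG (xoshiro256++ seeded via splitmix64), independent of R's
// RNG so that an integer seed fixes every simulated artifact byte-for-byte.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double exp1() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return -std::log(u);
  }
  inline int below(int n) { return (int)(unif() * n); }
  int pois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { k++; p *= unif(); } while (p > L);
      return k - 1;
    }
    double u;
    do { u = unif(); } while (u <= 0.0);
    double z = std::sqrt(-2.0 * std::log(u)) * std::cos(2.0 * M_PI * unif());
    double k = std::floor(lambda + std::sqrt(lambda) * z + 0.5);
    return k < 0 ? 0 : (int)k;
  }
};

// Demographic events, backward in time. kind: 0 = split (all lineages of pop
// `a` move to pop `b`), 1 = admixture pulse (each lineage of `a` moves to `b`
// with probability `par`), 2 = size change (pop `a` gets diploid size `par`),
// 3 = migration-rate change (per-lineage backward rate `a` -> `b` set to
// `par`). Continuous migration moves single lineages at exponential rate.
struct EventTable {
  int nev;
  const double* time;
  const int* kind;
  const int* a;
  const int* b;
  const double* par;
};

struct TreeBuf {
  std::vector<int> parent, lchild, rchild;
  std::vector<double> ntime;
  std::vector<std::vector<int>> members;
  std::vector<double> Ne;
  std::vector<double> mig;      // npop x npop, row-major: rate a -> b
  std::vector<double> mig_out;  // per-pop total outward rate
  void resize(int n, int npop) {
    parent.assign(2 * n - 1, -1);
    lchild.assign(2 * n - 1, -1);
    rchild.assign(2 * n - 1, -1);
    ntime.assign(2 * n - 1, 0.0);
    members.resize(npop);
    for (int p = 0; p < npop; p++) members[p].clear();
  }
};

// Simulate one coalescent genealogy; continuous time in generations,
// pairwise coalescence rate k(k-1)/(4 Ne) per population (diploid scaling).
static void sim_tree(Xoshiro& rng, int npop, const double* Ne0,
                     const double* mig0, const EventTable& ev,
                     const std::vector<int>& nsamp, int n, TreeBuf& tb) {
  tb.resize(n, npop);
  tb.Ne.assign(Ne0, Ne0 + npop);
  tb.mig.assign(mig0, mig0 + npop * npop);
  tb.mig_out.assign(npop, 0.0);
  bool any_mig = false;
  for (int p = 0; p < npop; p++) {
    double s = 0.0;
    for (int q = 0; q < npop; q++) s += tb.mig[p * npop + q];
    tb.mig_out[p] = s;
    if (s > 0.0) any_mig = true;
  }
  int id = 0;
  for (int p = 0; p < npop; p++)
    for (int i = 0; i < nsamp[p]; i++) tb.members[p].push_back(id++);
  int next_node = n, k = n, ei = 0;
  double t = 0.0;
  // Residual-exponential waiting times: one exp draw per realized
  // coalescence/migration, rescaled across rate changes (memorylessness).
  // Demographic events therefore consume no randomness, so models that
  // differ only by no-op events share the same stream.
  double W = rng.exp1();
  while (k > 1) {
    double Rc = 0.0, Rm = 0.0;
    for (int p = 0; p < npop; p++) {
      int m = (int)tb.members[p].size();
      if (m > 1) Rc += (double)m * (m - 1) / (4.0 * tb.Ne[p]);
      if (any_mig && m > 0) Rm += (double)m * tb.mig_out[p];
    }
    double R = Rc + Rm;
    double t_next = (ei < ev.nev) ? ev.time[ei] : R_PosInf;
    double dt = (R > 0.0) ? W / R : R_PosInf;
    if (t + dt >= t_next) {
      if (!R_FINITE(t_next))
        stop("remaining lineages cannot coalesce: model does not end in a single ancestral population");
      if (R > 0.0) W -= (t_next - t) * R;
      t = t_next;
      int kind = ev.kind[ei], ea = ev.a[ei], eb = ev.b[ei];
      double par = ev.par[ei];
      ei++;
      if (kind == 0) {
        for (size_t i = 0; i < tb.members[ea].size(); i++)
          tb.members[eb].push_back(tb.members[ea][i]);
        tb.members[ea].clear();
      } else if (kind == 1) {
        // boundary pulses consume no randomness, so alpha = 0 / alpha = 1
        // reproduce the corresponding pure-split models exactly
        if (par >= 1.0) {
          for (size_t i = 0; i < tb.members[ea].size(); i++)
            tb.members[eb].push_back(tb.members[ea][i]);
          tb.members[ea].clear();
        } else if (par > 0.0) {
          for (int i = (int)tb.members[ea].size() - 1; i >= 0; i--) {
            if (rng.unif() < par) {
              tb.members[eb].push_back(tb.members[ea][i]);
              tb.members[ea][i] = tb.members[ea].back();
              tb.members[ea].pop_back();
            }
          }
        }
      } else if (kind == 2) {
        tb.Ne[ea] = par;
      } else {
        tb.mig_out[ea] += par - tb.mig[ea * npop + eb];
        tb.mig[ea * npop + eb] = par;
        any_mig = false;
        for (int p = 0; p < npop; p++)
          if (tb.mig_out[p] > 0.0) any_mig = true;
      }
      continue;
    }
    t += dt;
    W = rng.exp1();
    double u = rng.unif() * R;
    if (u >= Rc) {
      // continuous migration: move one lineage from p to q
      double um = u - Rc, acc = 0.0;
      int mp = -1, mq = -1;
      for (int p = 0; p < npop && mp < 0; p++) {
        int m = (int)tb.members[p].size();
        if (m == 0 || tb.mig_out[p] <= 0.0) continue;
        for (int q = 0; q < npop; q++) {
          double rate = (double)m * tb.mig[p * npop + q];
          if (rate <= 0.0) continue;
          acc += rate;
          if (um < acc) { mp = p; mq = q; break; }
        }
      }
      if (mp < 0) continue;  // numerical edge: no migration applicable
      std::vector<int>& mem = tb.members[mp];
      int i = rng.below((int)mem.size());
      tb.members[mq].push_back(mem[i]);
      mem[i] = mem.back();
      mem.pop_back();
      continue;
    }
    double acc = 0.0;
    int p = -1;
    for (int q = 0; q < npop; q++) {
      int m = (int)tb.members[q].size();
      if (m > 1) {
        acc += (double)m * (m - 1) / (4.0 * tb.Ne[q]);
        if (u < acc) { p = q; break; }
      }
    }
    if (p < 0) p = npop - 1;
    std::vector<int>& mem = tb.members[p];
    int m = (int)mem.size();
    int i = rng.below(m);
    int j = rng.below(m - 1);
    if (j >= i) j++;
    int u1 = mem[i], u2 = mem[j];
    int w = next_node++;
    tb.parent[u1] = w; tb.parent[u2] = w;
    tb.lchild[w] = u1; tb.rchild[w] = u2;
    tb.ntime[w] = t;
    int lo = std::min(i, j), hi = std::max(i, j);
    mem[lo] = w;
    mem[hi] = mem.back();
    mem.pop_back();
    k--;
  }
}

// Joint SFS over n_sims single-SNP genealogies: one mutation per genealogy on
// a branch drawn proportional to branch length (per-SNP simulation).
// [[Rcpp::export]]
IntegerVector cpp_sfs_counts(NumericVector Ne0, NumericVector mig,
                             NumericVector ev_time,
                             IntegerVector ev_kind, IntegerVector ev_a,
                             IntegerVector ev_b, NumericVector ev_par,
                             IntegerVector nsamp, int n_sims, double seed) {
  int npop = Ne0.size();
  std::vector<int> ns(nsamp.begin(), nsamp.end());
  int n = 0;
  for (int p = 0; p < npop; p++) n += ns[p];
  if (n < 2) stop("need at least two sampled haplotypes");
  EventTable ev = {(int)ev_time.size(), ev_time.begin(), ev_kind.begin(),
                   ev_a.begin(), ev_b.begin(), ev_par.begin()};
  // strides over sampled populations only (dims nsamp + 1)
  std::vector<int> spop;  // sampled pop ids
  std::vector<int> stride;
  int ncell = 1;
  for (int p = 0; p < npop; p++) {
    if (ns[p] > 0) {
      spop.push_back(p);
      stride.push_back(ncell);
      ncell *= ns[p] + 1;
    }
  }
  int nsp = (int)spop.size();
  IntegerVector out(ncell);
  Xoshiro rng((uint64_t)seed + 0x5DEECE66DULL);
  TreeBuf tb;
  std::vector<double> blen(2 * n - 1);
  std::vector<int> cnt((2 * n - 1) * nsp);
  std::vector<int> leaf_sp(n);
  {
    int id = 0, si = 0;
    for (int p = 0; p < npop; p++) {
      if (ns[p] == 0) continue;
      for (int i = 0; i < ns[p]; i++) leaf_sp[id++] = si;
      si++;
    }
  }
  for (int s = 0; s < n_sims; s++) {
    sim_tree(rng, npop, Ne0.begin(), mig.begin(), ev, ns, n, tb);
    // per-node descendant counts by sampled pop; nodes created in time order
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int v = 0; v < n; v++) cnt[v * nsp + leaf_sp[v]] = 1;
    for (int v = n; v < 2 * n - 1; v++) {
      int l = tb.lchild[v], r = tb.rchild[v];
      for (int q = 0; q < nsp; q++)
        cnt[v * nsp + q] = cnt[l * nsp + q] + cnt[r * nsp + q];
    }
    double tot = 0.0;
    for (int v = 0; v < 2 * n - 2; v++) {
      blen[v] = tb.ntime[tb.parent[v]] - tb.ntime[v];
      tot += blen[v];
    }
    double u = rng.unif() * tot, acc = 0.0;
    int pick = 2 * n - 3;
    for (int v = 0; v < 2 * n - 2; v++) {
      acc += blen[v];
      if (u < acc) { pick = v; break; }
    }
    int idx = 0;
    for (int q = 0; q < nsp; q++) idx += cnt[pick * nsp + q] * stride[q];
    out[idx]++;
  }
  return out;
}

// Full simulator: per locus returns the genealogy (parent pointers, node
// times in generations) and a haplotype x site 0/1 genotype matrix.
// mode 0 = sequence (infinite-sites Poisson mutations at rate mu per site per
// generation), mode 1 = snp (exactly one site, branch drawn prop. to length).
// [[Rcpp::export]]
List cpp_simulate(NumericVector Ne0, NumericVector mig,
                  NumericVector ev_time,
                  IntegerVector ev_kind, IntegerVector ev_a,
                  IntegerVector ev_b, NumericVector ev_par,
                  IntegerVector nsamp, int n_loci, double locus_len,
                  double mu, int mode, double seed) {
  int npop = Ne0.size();
  std::vector<int> ns(nsamp.begin(), nsamp.end());
  int n = 0;
  for (int p = 0; p < npop; p++) n += ns[p];
  if (n < 2) stop("need at least two sampled haplotypes");
  EventTable ev = {(int)ev_time.size(), ev_time.begin(), ev_kind.begin(),
                   ev_a.begin(), ev_b.begin(), ev_par.begin()};
  Xoshiro rng((uint64_t)seed + 0x5DEECE66DULL);
  TreeBuf tb;
  std::vector<double> blen(2 * n - 1);
  std::vector<int> stack;
  List loci(n_loci);
  for (int loc = 0; loc < n_loci; loc++) {
    sim_tree(rng, npop, Ne0.begin(), mig.begin(), ev, ns, n, tb);
    double tot = 0.0;
    for (int v = 0; v < 2 * n - 2; v++) {
      blen[v] = tb.ntime[tb.parent[v]] - tb.ntime[v];
      tot += blen[v];
    }
    int nmut;
    if (mode == 1) {
      nmut = 1;
    } else {
      nmut = rng.pois(mu * locus_len * tot);
      if (nmut > (int)locus_len) nmut = (int)locus_len;  // infinite sites cap
    }
    std::vector<int> mpos(nmut), mnode(nmut);
    std::vector<bool> used;
    if (mode == 0 && nmut > 0) used.assign((size_t)locus_len, false);
    for (int m = 0; m < nmut; m++) {
      double u = rng.unif() * tot, acc = 0.0;
      int pick = 2 * n - 3;
      for (int v = 0; v < 2 * n - 2; v++) {
        acc += blen[v];
        if (u < acc) { pick = v; break; }
      }
      mnode[m] = pick;
      if (mode == 1) {
        mpos[m] = 0;
      } else {
        int pos;
        do { pos = rng.below((int)locus_len); } while (used[pos]);
        used[pos] = true;
        mpos[m] = pos;
      }
    }
    // sort mutations by position
    std::vector<int> ord(nmut);
    for (int m = 0; m < nmut; m++) ord[m] = m;
    std::sort(ord.begin(), ord.end(),
              [&](int x, int y) { return mpos[x] < mpos[y]; });
    IntegerMatrix G(n, nmut);
    IntegerVector pos(nmut);
    for (int c = 0; c < nmut; c++) {
      int m = ord[c];
      pos[c] = mpos[m];
      stack.clear();
      stack.push_back(mnode[m]);
      while (!stack.empty()) {
        int x = stack.back();
        stack.pop_back();
        if (x < n) {
          G(x, c) = 1;
        } else {
          stack.push_back(tb.lchild[x]);
          stack.push_back(tb.rchild[x]);
        }
      }
    }
    loci[loc] = List::create(
        _["parent"] = IntegerVector(tb.parent.begin(), tb.parent.end()),
        _["time"] = NumericVector(tb.ntime.begin(), tb.ntime.end()),
        _["pos"] = pos, _["geno"] = G);
  }
  return loci;
}

// Topology weights for one genealogy: repeatedly draw one leaf per group and
// classify the rooted triple (which pair coalesces most recently). Returns
// counts for cherries (A,B), (A,C), (B,C).
// [[Rcpp::export]]
IntegerVector cpp_topo_counts(IntegerVector parent, NumericVector ntime,
                              IntegerVector leaves_a, IntegerVector leaves_b,
                              IntegerVector leaves_c, int n_samples,
                              double seed) {
  int nn = parent.size();
  Xoshiro rng((uint64_t)seed + 0x9E3779B9ULL);
  std::vector<int> stamp(nn, -1);
  IntegerVector out(3);
  for (int s = 0; s < n_samples; s++) {
    int a = leaves_a[rng.below(leaves_a.size())];
    int b = leaves_b[rng.below(leaves_b.size())];
    int c = leaves_c[rng.below(leaves_c.size())];
    int trio[3] = {a, b, c};
    double tm[3];  // MRCA times ab, ac, bc
    int pair_i[3] = {0, 0, 1}, pair_j[3] = {1, 2, 2};
    for (int q = 0; q < 3; q++) {
      int x = trio[pair_i[q]], y = trio[pair_j[q]];
      int v = x;
      while (v != -1) { stamp[v] = s * 3 + q; v = parent[v]; }
      v = y;
      while (stamp[v] != s * 3 + q) v = parent[v];
      tm[q] = ntime[v];
    }
    int best = 0;
    if (tm[1] < tm[best]) best = 1;
    if (tm[2] < tm[best]) best = 2;
    out[best]++;
  }
  return out;
}
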