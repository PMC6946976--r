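#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Haplotype layout: states/labels are L x 2N integer matrices, individual i
// (0-based) owns columns 2i (paternal) and 2i+1 (maternal).  Loci are grouped
// by chromosome; chromStart holds 0-based row offsets of length nChrom + 1.
// Genetic length of every chromosome is 1 Morgan; the n loci of a chromosome
// sit at positions (j + 0.5)/n, j = 0..n-1.

// Draw one gamete for one chromosome.  Crossover count ~ Poisson(1), each
// crossover position uniform on (0, 1) Morgan; the source haplotype starts
// from a fair coin and switches at every crossover.  States and labels travel
// together: the label is physically linked to its allele copy.
// src (optional, length n) records the source haplotype (0/1) per locus.
static int gamete_chrom(const int* a_st, const int* b_st,
                        const int* a_lb, const int* b_lb, bool haveLb,
                        int n, int* out_st, int* out_lb, int* src) {
  int ncross = (int) R::rpois(1.0);
  // convert crossover positions to cut indices: a crossover at u switches the
  // source for all loci with position > u, i.e. starting at locus
  // k = #{j : (j + 0.5)/n <= u}
  int cuts[64];
  if (ncross > 64) ncross = 64; // Poisson(1) beyond 64 is impossible in practice
  for (int c = 0; c < ncross; ++c) {
    double u = unif_rand();
    int k = (int) (u * n + 0.5);
    if (k > n) k = n;
    cuts[c] = k;
  }
  std::sort(cuts, cuts + ncross);
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  int pos = 0, ci = 0;
  while (pos < n) {
    // every cut at the current position toggles the source (two crossovers
    // falling in the same inter-locus interval cancel)
    while (ci < ncross && cuts[ci] == pos) { cur = 1 - cur; ++ci; }
    int stop = (ci < ncross && cuts[ci] < n) ? cuts[ci] : n;
    const int* s = (cur == 0) ? a_st : b_st;
    std::memcpy(out_st + pos, s + pos, (stop - pos) * sizeof(int));
    if (haveLb) {
      const int* l = (cur == 0) ? a_lb : b_lb;
      std::memcpy(out_lb + pos, l + pos, (stop - pos) * sizeof(int));
    }
    if (src) for (int j = pos; j < stop; ++j) src[j] = cur;
    pos = stop;
  }
  return ncross;
}

static inline int runif_int(int n) {
  int k = (int) (unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Full burn-in: all loci start fixed at state 1; nGen generations of random
// mating (uniform sire among the Nm males, uniform dam among the Nf females,
// drawn independently per offspring) with Poisson(mutMean) state-flip
// mutations per generation.  Labels are not tracked before t = 0.
// Returns the final L x 2N state matrix plus a mean-He trace (all raw loci)
// recorded every heEvery generations.
// [[Rcpp::export]]
List cpp_burnin(int nLociPerChrom, int nChrom, int Nm, int Nf,
                int nGen, double mutMean, int heEvery) {
  const int N = Nm + Nf, L = nLociPerChrom * nChrom, H = 2 * N;
  IntegerMatrix cur(L, H), nxt(L, H);
  std::fill(cur.begin(), cur.end(), 1);
  IntegerVector chromStart(nChrom + 1);
  for (int c = 0; c <= nChrom; ++c) chromStart[c] = c * nLociPerChrom;
  std::vector<double> traceGen, traceHe;
  for (int t = 1; t <= nGen; ++t) {
    for (int k = 0; k < N; ++k) {
      int sire = runif_int(Nm);
      int dam  = Nm + runif_int(Nf);
      for (int g = 0; g < 2; ++g) {
        int par = (g == 0) ? sire : dam;
        const int* a = &cur(0, 2 * par);
        const int* b = &cur(0, 2 * par + 1);
        int* out = &nxt(0, 2 * k + g);
        for (int c = 0; c < nChrom; ++c) {
          int off = chromStart[c];
          gamete_chrom(a + off, b + off, nullptr, nullptr, false,
                       nLociPerChrom, out + off, nullptr, nullptr);
        }
      }
    }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
    int K = (int) R::rpois(mutMean);
    for (int m = 0; m < K; ++m) {
      int col = runif_int(H), row = runif_int(L);
      cur(row, col) = 3 - cur(row, col); // flip 1<->2
    }
    if (heEvery > 0 && (t % heEvery == 0 || t == nGen)) {
      double he = 0.0;
      for (int l = 0; l < L; ++l) {
        int n2 = 0;
        for (int h = 0; h < H; ++h) n2 += (cur(l, h) == 2);
        double p = (double) n2 / H;
        he += 2.0 * p * (1.0 - p);
      }
      traceGen.push_back(t - nGen); // relative to t = 0 at burn-in end
      traceHe.push_back(he / L);
    }
    if (t % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["states"] = cur,
                      _["traceGeneration"] = wrap(traceGen),
                      _["traceHe"] = wrap(traceHe));
}

// Produce an offspring pool: offspring k gets a paternal gamete from
// individual sire0[k] and a maternal gamete from dam0[k] (0-based indices
// into the parent population's individuals).
// [[Rcpp::export]]
List cpp_offspring(IntegerMatrix st, IntegerMatrix lb, bool haveLb,
                   IntegerVector sire0, IntegerVector dam0,
                   IntegerVector chromStart) {
  const int L = st.nrow(), nOff = sire0.size(), nChrom = chromStart.size() - 1;
  IntegerMatrix ost(L, 2 * nOff);
  IntegerMatrix olb(haveLb ? L : 0, haveLb ? 2 * nOff : 0);
  for (int k = 0; k < nOff; ++k) {
    for (int g = 0; g < 2; ++g) {
      int par = (g == 0) ? sire0[k] : dam0[k];
      const int* a_st = &st(0, 2 * par);
      const int* b_st = &st(0, 2 * par + 1);
      const int* a_lb = haveLb ? &lb(0, 2 * par) : nullptr;
      const int* b_lb = haveLb ? &lb(0, 2 * par + 1) : nullptr;
      int* o_st = &ost(0, 2 * k + g);
      int* o_lb = haveLb ? &olb(0, 2 * k + g) : nullptr;
      for (int c = 0; c < nChrom; ++c) {
        int off = chromStart[c], n = chromStart[c + 1] - off;
        gamete_chrom(a_st + off, b_st + off,
                     haveLb ? a_lb + off : nullptr,
                     haveLb ? b_lb + off : nullptr, haveLb,
                     n, o_st + off, haveLb ? o_lb + off : nullptr, nullptr);
      }
    }
  }
  return List::create(_["states"] = ost, _["labels"] = olb);
}

// One gamete from one parent, optionally recording crossover counts per
// chromosome and the per-locus source haplotype (0/1).
// [[Rcpp::export]]
List cpp_gamete(IntegerMatrix st, IntegerMatrix lb, bool haveLb,
                int indiv0, IntegerVector chromStart, bool record) {
  const int L = st.nrow(), nChrom = chromStart.size() - 1;
  IntegerVector o_st(L), o_lb(haveLb ? L : 0);
  IntegerVector ncross(nChrom), src(record ? L : 0);
  const int* a_st = &st(0, 2 * indiv0);
  const int* b_st = &st(0, 2 * indiv0 + 1);
  const int* a_lb = haveLb ? &lb(0, 2 * indiv0) : nullptr;
  const int* b_lb = haveLb ? &lb(0, 2 * indiv0 + 1) : nullptr;
  for (int c = 0; c < nChrom; ++c) {
    int off = chromStart[c], n = chromStart[c + 1] - off;
    ncross[c] = gamete_chrom(a_st + off, b_st + off,
                             haveLb ? a_lb + off : nullptr,
                             haveLb ? b_lb + off : nullptr, haveLb, n,
                             &o_st[off], haveLb ? &o_lb[off] : nullptr,
                             record ? &src[off] : nullptr);
  }
  return List::create(_["states"] = o_st, _["labels"] = o_lb,
                      _["crossovers"] = ncross, _["source"] = src);
}

// Per-locus count of cross-individual haplotype pairings that match on state
// (useLabels = false) or on state AND founder label (useLabels = true).
// The denominator per locus is choose(2N, 2) - N: all unordered haplotype
// pairs from distinct individuals (equivalently, for every unordered pair of
// individuals, all 4 cross-individual allele pairings).
// [[Rcpp::export]]
NumericVector cpp_identity_counts(IntegerMatrix st, IntegerMatrix lb,
                                  bool useLabels) {
  const int L = st.nrow(), H = st.ncol(), N = H / 2;
  int maxLb = 1;
  if (useLabels) {
    for (int i = 0; i < lb.size(); ++i) if (lb[i] > maxLb) maxLb = lb[i];
  }
  const int nkey = 2 * (maxLb + 1);
  std::vector<int> cnt(nkey);
  NumericVector out(L);
  for (int l = 0; l < L; ++l) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int h = 0; h < H; ++h) {
      int key = (st(l, h) - 1) * (maxLb + 1) + (useLabels ? lb(l, h) : 0);
      ++cnt[key];
    }
    double tot = 0.0;
    for (int k = 0; k < nkey; ++k)
      if (cnt[k] > 1) tot += (double) cnt[k] * (cnt[k] - 1) / 2.0;
    // remove within-individual matches
    for (int i = 0; i < N; ++i) {
      bool same = st(l, 2 * i) == st(l, 2 * i + 1) &&
        (!useLabels || lb(l, 2 * i) == lb(l, 2 * i + 1));
      if (same) tot -= 1.0;
    }
    out[l] = tot;
  }
  return out;
}
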