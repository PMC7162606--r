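#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Crossover model: count per chromosome ~ Poisson(length_cM / 100), positions
// uniform along the chromosome, no interference (Haldane). Mutation is a
// recurrent biallelic flip applied to the transmitted allele.

template <typename T>
static void make_one_gamete(const T* hapA, const T* hapB,
                            T* out,
                            const std::vector<int>& chromStart,
                            const std::vector<int>& chromEnd,
                            const NumericVector& chromLen,
                            const NumericVector& pos,
                            double mutRate) {
  int nChrom = chromLen.size();
  std::vector<double> xo;
  for (int c = 0; c < nChrom; ++c) {
    int s = chromStart[c], e = chromEnd[c];
    double len = chromLen[c];
    int nxo = (len > 0.0) ? (int) R::rpois(len / 100.0) : 0;
    xo.clear();
    for (int k = 0; k < nxo; ++k) xo.push_back(unif_rand() * len);
    std::sort(xo.begin(), xo.end());
    int strand = (unif_rand() < 0.5) ? 0 : 1;
    // copy contiguous segments between crossovers
    int i = s;
    for (size_t k = 0; k <= xo.size(); ++k) {
      int stop = e;
      if (k < xo.size()) {
        // a locus at exactly the crossover position is transmitted on the
        // flipped strand
        stop = (int) (std::lower_bound(pos.begin() + i, pos.begin() + e, xo[k])
                      - pos.begin());
      }
      if (stop > i) {
        const T* src = strand ? hapB : hapA;
        std::copy(src + i, src + stop, out + i);
        i = stop;
      }
      strand ^= 1;
    }
    if (i < e) {
      // trailing segment when the last crossover sits beyond all loci
      const T* src = strand ? hapB : hapA;
      std::copy(src + i, src + e, out + i);
    }
  }
  if (mutRate > 0.0) {
    int nLoci = pos.size();
    int nmut = (int) R::rbinom((double) nLoci, mutRate);
    for (int k = 0; k < nmut; ++k) {
      int i = (int) (unif_rand() * nLoci);
      if (i >= nLoci) i = nLoci - 1;
      out[i] = 1 - out[i];
    }
  }
}

static void chrom_bounds(const IntegerVector& chromIndex, int nChrom,
                         std::vector<int>& start, std::vector<int>& end) {
  // chromIndex: 1-based chromosome id per locus, loci grouped and ordered
  int n = chromIndex.size();
  start.assign(nChrom, 0);
  end.assign(nChrom, 0);
  for (int c = 0; c < nChrom; ++c) { start[c] = n; end[c] = 0; }
  for (int i = 0; i < n; ++i) {
    int c = chromIndex[i] - 1;
    if (i < start[c]) start[c] = i;
    if (i + 1 > end[c]) end[c] = i + 1;
  }
  for (int c = 0; c < nChrom; ++c) if (start[c] > end[c]) { start[c] = 0; end[c] = 0; }
}

// [[Rcpp::export(name = ".cpp_make_gametes")]]
IntegerMatrix cpp_make_gametes(IntegerMatrix hapA, IntegerMatrix hapB,
                               IntegerVector chromIndex, NumericVector chromLen,
                               NumericVector pos, double mutRate) {
  // hapA/hapB: one row per gamete to be produced = the two strands of the
  // chosen parent, loci in columns. Returns gametes in the same layout.
  int n = hapA.nrow(), m = hapA.ncol();
  if (hapB.nrow() != n || hapB.ncol() != m)
    stop("strand matrices must have identical dimensions");
  int nChrom = chromLen.size();
  std::vector<int> cs, ce;
  chrom_bounds(chromIndex, nChrom, cs, ce);
  IntegerMatrix out(n, m);
  std::vector<int> a(m), b(m), g(m);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < m; ++i) { a[i] = hapA(r, i); b[i] = hapB(r, i); }
    make_one_gamete<int>(a.data(), b.data(), g.data(), cs, ce, chromLen, pos,
                         mutRate);
    for (int i = 0; i < m; ++i) out(r, i) = g[i];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sim_history")]]
List cpp_sim_history(IntegerVector chromIndex, NumericVector chromLen,
                     NumericVector pos, double mutRate,
                     IntegerVector phaseSizes, IntegerVector phaseGens) {
  // Discrete non-overlapping generations of random mating at constant size
  // within each phase; equal sex ratio (first half of each generation male).
  // Initial allele frequency is exactly 0.50 at every locus: half of the
  // 2N founder haplotypes carry allele 1, in random order.
  int m = pos.size();
  int nChrom = chromLen.size();
  std::vector<int> cs, ce;
  chrom_bounds(chromIndex, nChrom, cs, ce);

  int nPhase = phaseSizes.size();
  if (phaseGens.size() != nPhase) stop("phaseSizes/phaseGens length mismatch");
  int n0 = phaseSizes[0];
  if (n0 < 2) stop("historical population needs at least 2 individuals");

  // current generation buffers: two strands per individual (byte storage:
  // the generation loop is memory-bandwidth bound)
  std::vector<std::vector<char>> h1(n0, std::vector<char>(m)),
      h2(n0, std::vector<char>(m));
  {
    std::vector<int> pool(2 * n0);
    for (int j = 0; j < m; ++j) {
      for (int k = 0; k < 2 * n0; ++k) pool[k] = (k < n0) ? 1 : 0;
      // Fisher-Yates with R RNG
      for (int k = 2 * n0 - 1; k > 0; --k) {
        int r = (int) (unif_rand() * (k + 1));
        if (r > k) r = k;
        std::swap(pool[k], pool[r]);
      }
      for (int i = 0; i < n0; ++i) {
        h1[i][j] = (char) pool[2 * i];
        h2[i][j] = (char) pool[2 * i + 1];
      }
    }
  }

  int nCur = n0;
  std::vector<std::vector<char>> n1(0), n2(0);
  for (int p = 0; p < nPhase; ++p) {
    int nNext = phaseSizes[p];
    for (int g = 0; g < phaseGens[p]; ++g) {
      int nMalesCur = nCur / 2;
      int nFemCur = nCur - nMalesCur;
      n1.assign(nNext, std::vector<char>(m));
      n2.assign(nNext, std::vector<char>(m));
      for (int i = 0; i < nNext; ++i) {
        int sire = (int) (unif_rand() * nMalesCur);
        if (sire >= nMalesCur) sire = nMalesCur - 1;
        int dam = nMalesCur + (int) (unif_rand() * nFemCur);
        if (dam >= nCur) dam = nCur - 1;
        make_one_gamete(h1[sire].data(), h2[sire].data(), n1[i].data(),
                        cs, ce, chromLen, pos, mutRate);
        make_one_gamete(h1[dam].data(), h2[dam].data(), n2[i].data(),
                        cs, ce, chromLen, pos, mutRate);
      }
      h1.swap(n1);
      h2.swap(n2);
      nCur = nNext;
    }
  }

  IntegerMatrix out1(nCur, m), out2(nCur, m);
  for (int i = 0; i < nCur; ++i)
    for (int j = 0; j < m; ++j) { out1(i, j) = h1[i][j]; out2(i, j) = h2[i][j]; }
  // sex: first half male, mirrors the mating scheme above
  IntegerVector sex(nCur);
  for (int i = 0; i < nCur; ++i) sex[i] = (i < nCur / 2) ? 1 : 2;
  return List::create(_["hap1"] = out1, _["hap2"] = out2, _["sex"] = sex);
}
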