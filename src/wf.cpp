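#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Advance a Wright-Fisher population `gens` generations at diploid size
// `ne`, starting from the haplotype pool `init` (rows = haplotypes, pairs of
// rows = diploids). chrom_start gives the 0-based first site of each
// chromosome, morgan the within-chromosome genetic coordinate of each site
// (starting near 0) and L each chromosome's genetic length in Morgan.
// [[Rcpp::export(name = ".wf_evolve_cpp")]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix init, int gens, int ne,
                            IntegerVector chrom_start, NumericVector morgan,
                            NumericVector L) {
  const int S = init.ncol();
  const int nchr = chrom_start.size();
  const int Hout = 2 * ne;
  // site-major buffers: hap h occupies [S*h, S*(h+1))
  std::vector<int> cur((size_t)S * std::max(init.nrow(), Hout));
  std::vector<int> nxt((size_t)S * Hout);
  int Hcur = init.nrow();
  for (int h = 0; h < Hcur; ++h)
    for (int s = 0; s < S; ++s) cur[(size_t)S * h + s] = init(h, s);
  std::vector<double> bp;
  for (int g = 0; g < gens; ++g) {
    const int np = Hcur / 2;
    for (int h = 0; h < Hout; ++h) {
      const int p = (int)(unif_rand() * np) % np;
      int* dst = &nxt[(size_t)S * h];
      for (int c = 0; c < nchr; ++c) {
        const int s0 = chrom_start[c];
        const int s1 = (c + 1 < nchr) ? chrom_start[c + 1] : S;
        int phase = (unif_rand() < 0.5) ? 0 : 1;
        int ncross = (L[c] > 0.0) ? (int)R::rpois(L[c]) : 0;
        if (ncross == 0) {
          const int* src = &cur[(size_t)S * (2 * p + phase)];
          for (int s = s0; s < s1; ++s) dst[s] = src[s];
        } else {
          bp.resize(ncross);
          for (int x = 0; x < ncross; ++x) bp[x] = unif_rand() * L[c];
          std::sort(bp.begin(), bp.end());
          const int* src1 = &cur[(size_t)S * (2 * p)];
          const int* src2 = &cur[(size_t)S * (2 * p + 1)];
          int x = 0;
          for (int s = s0; s < s1; ++s) {
            while (x < ncross && bp[x] <= morgan[s]) { ++x; phase ^= 1; }
            dst[s] = (phase == 0) ? src1[s] : src2[s];
          }
        }
      }
    }
    std::swap(cur, nxt);
    Hcur = Hout;
  }
  IntegerMatrix out(Hcur, S);
  for (int h = 0; h < Hcur; ++h)
    for (int s = 0; s < S; ++s) out(h, s) = cur[(size_t)S * h + s];
  return out;
}

// Gametes for one chromosome: each gamete is a recombinant copy of the two
// haplotypes (rows 2i, 2i+1) of its diploid parent. Crossover count is
// Poisson(L) with L the chromosome's genetic length in Morgan; crossover
// positions are uniform on (0, L) and sites are located by their Morgan
// coordinate. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".wf_gametes_cpp")]]
IntegerMatrix wf_gametes_cpp(IntegerMatrix parents, IntegerVector parent_idx,
                             NumericVector morgan, double L) {
  const int S = parents.ncol();
  if ((int)morgan.size() != S) stop("morgan coordinates do not match sites");
  const int n = parent_idx.size();
  IntegerMatrix out(n, S);
  std::vector<double> bp;
  for (int g = 0; g < n; ++g) {
    const int p = parent_idx[g]; // 0-based diploid index
    const int r1 = 2 * p, r2 = 2 * p + 1;
    int phase = (unif_rand() < 0.5) ? 0 : 1;
    int ncross = (L > 0.0) ? (int)R::rpois(L) : 0;
    if (ncross == 0) {
      const int src = phase == 0 ? r1 : r2;
      for (int s = 0; s < S; ++s) out(g, s) = parents(src, s);
    } else {
      bp.resize(ncross);
      for (int c = 0; c < ncross; ++c) bp[c] = unif_rand() * L;
      std::sort(bp.begin(), bp.end());
      int c = 0;
      for (int s = 0; s < S; ++s) {
        while (c < ncross && bp[c] <= morgan[s]) { ++c; phase ^= 1; }
        out(g, s) = parents(phase == 0 ? r1 : r2, s);
      }
    }
  }
  return out;
}
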