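#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sample n gametes from one individual by a crossover process with no
// interference: per chromosome the crossover count is Poisson with mean equal
// to the chromosome map length (Morgans) and crossover positions are uniform
// on the map, which makes the recombination fraction between two sites the
// Haldane value for their map distance.
//
// hap: 2 x S matrix, the individual's two haplotypes over all sites
// pos: within-chromosome map position (Morgans) of each site, ordered
// chrom_sites: number of sites on each chromosome (sums to S)
// chrom_len: map length (Morgans) of each chromosome
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix hap, const int n,
                          const NumericVector pos,
                          const IntegerVector chrom_sites,
                          const NumericVector chrom_len) {
  const int S = hap.ncol();
  const int C = chrom_sites.size();
  IntegerMatrix out(n, S);
  std::vector<double> xo;
  for (int g = 0; g < n; ++g) {
    int off = 0;
    for (int c = 0; c < C; ++c) {
      const int m = chrom_sites[c];
      const double len = chrom_len[c];
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      const int nco = (int) R::rpois(len);
      if (nco == 0) {
        for (int i = 0; i < m; ++i) out(g, off + i) = hap(cur, off + i);
      } else {
        xo.resize(nco);
        for (int k = 0; k < nco; ++k) xo[k] = unif_rand() * len;
        std::sort(xo.begin(), xo.end());
        int k = 0;
        for (int i = 0; i < m; ++i) {
          const double p = pos[off + i];
          while (k < nco && xo[k] < p) { cur ^= 1; ++k; }
          out(g, off + i) = hap(cur, off + i);
        }
      }
      off += m;
    }
  }
  return out;
}
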