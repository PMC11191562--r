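#include <Rcpp.h>
using namespace Rcpp;

// Diploid genotypes from the block-copy haplotype process.
// Two haplotype chains are advanced SNP by SNP: within a block, each
// haplotype copies its previous allele with probability `decay`,
// otherwise redraws Bernoulli(maf). Blocks restart the chains.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".simGenotypesC")]]
IntegerMatrix sim_genotypes_c(NumericVector maf, IntegerVector blockSizes,
                              double decay, int n) {
    int M = maf.size();
    IntegerMatrix G(n, M);
    std::vector<int> h1(n), h2(n);
    int j = 0;
    for (int b = 0; b < blockSizes.size(); ++b) {
        for (int s = 0; s < blockSizes[b]; ++s, ++j) {
            double m = maf[j];
            if (s == 0) {
                for (int i = 0; i < n; ++i) {
                    h1[i] = unif_rand() < m;
                    h2[i] = unif_rand() < m;
                    G(i, j) = h1[i] + h2[i];
                }
            } else {
                for (int i = 0; i < n; ++i) {
                    if (unif_rand() >= decay) h1[i] = unif_rand() < m;
                    if (unif_rand() >= decay) h2[i] = unif_rand() < m;
                    G(i, j) = h1[i] + h2[i];
                }
            }
        }
    }
    return G;
}
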