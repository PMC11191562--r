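# Core block-copy haplotype process: within each block, SNP s copies the
# allele at SNP s-1 with probability `decay`, else redraws Bernoulli(maf).
# Blocks are independent. Returns an nHap x M 0/1 integer matrix.
.simHaplotypes <- function(maf, blockSizes, decay, nHap,
                           fixMonomorphic = FALSE) {
    M <- sum(blockSizes)
    stopifnot(length(maf) == M)
    H <- matrix(0L, nHap, M)
    j <- 0L
    for (bs in blockSizes) {
        cols <- j + seq_len(bs)
        # bulk randomness per block, then run the copy chain column-wise
        B <- matrix(as.integer(runif(nHap * bs) <
                               rep(maf[cols], each = nHap)), nHap, bs)
        if (bs > 1L && decay > 0) {
            Keep <- matrix(runif(nHap * (bs - 1L)) < decay,
                           nHap, bs - 1L)
            for (s in 2:bs) {
                k <- Keep[, s - 1L]
                b <- B[, s]
                b[k] <- B[k, s - 1L]
                B[, s] <- b
            }
        }
        if (fixMonomorphic) {
            for (s in seq_len(bs)) {
                while (length(unique(B[, s])) < 2L)
                    B[, s] <- as.integer(runif(nHap) < maf[cols[s]])
            }
        }
        H[, cols] <- B
        j <- j + bs
    }
    H
}

#' Simulate a block-structured haplotype reference panel
#'
#' Haplotypes are generated by a first-order copy process within blocks:
#' at each SNP after the first in a block, each haplotype copies its
#' allele at the previous SNP with probability \code{decay} and otherwise
#' redraws a Bernoulli(maf) allele. Blocks are generated independently,
#' so the population r-squared between SNPs in different blocks is zero
#' by construction. Per-SNP target mafs are Uniform(0.05, 0.5). SNPs are
#' laid on chromosome \code{"chrG"} at regular \code{spacing}.
#'
#' Columns that come out monomorphic (possible at small \code{n_ind})
#' are redrawn at that SNP's maf until polymorphic, which breaks the copy
#' chain at that SNP only.
#'
#' @param n_ind number of diploid individuals (>= 2); the panel holds
#'   \code{2*n_ind} haplotypes.
#' @param n_blocks,block_size number and size of independent LD blocks;
#'   total SNPs M = n_blocks * block_size.
#' @param decay copy probability in [0,1); 0 gives mutually independent
#'   SNPs, values near 1 give long-range LD.
#' @param seed integer RNG seed.
#' @param spacing inter-SNP distance in bp (default 1000).
#' @return an \linkS4class{LDPanel}.
#' @examples
#' panel <- simulateLDPanel(50, n_blocks = 4, block_size = 10,
#'     decay = 0.9, seed = 1)
#' panel
#' @export
simulateLDPanel <- function(n_ind, n_blocks, block_size, decay, seed,
                            spacing = 1000L) {
    n_ind <- .assertCount(n_ind, "n_ind")
    if (n_ind < 2) stop("n_ind must be >= 2 (r-squared undefined otherwise)")
    n_blocks <- .assertCount(n_blocks, "n_blocks")
    block_size <- .assertCount(block_size, "block_size")
    if (!is.numeric(decay) || decay < 0 || decay >= 1)
        stop("'decay' must lie in [0, 1)")
    set.seed(.assertCount(seed, "seed", min = 0L))
    nHap <- 2L * n_ind
    M <- n_blocks * block_size
    maf <- runif(M, 0.05, 0.5)
    H <- .simHaplotypes(maf, rep(block_size, n_blocks), decay, nHap,
                        fixMonomorphic = TRUE)
    alleles <- c("A", "C", "G", "T")
    a1 <- sample(alleles, M, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1L), "")
    snpTable <- DataFrame(
        snp_id = sprintf("rs%06d", seq_len(M)),
        chrom = "chrG",
        pos = as.integer(seq_len(M)) * as.integer(spacing),
        a1 = a1, a2 = unname(a2), maf = maf,
        block = rep(seq_len(n_blocks), each = block_size))
    colnames(H) <- snpTable$snp_id
    new("LDPanel", haplotypes = H, snpTable = snpTable,
        blockBounds = as.integer(seq(1L, M, by = block_size)),
        decay = as.numeric(decay))
}

#' Pairwise LD (r-squared) table from a haplotype panel
#'
#' Sample r-squared between SNP pairs within the same LD block; pairs in
#' different blocks are independent by construction and are reported as
#' r-squared 0 (i.e. omitted unless \code{r2_min <= 0}).
#'
#' @param panel an \linkS4class{LDPanel}.
#' @param r2_min report only pairs with r-squared above this value.
#' @return \code{DataFrame} with columns snp_a, snp_b, r2 (each unordered
#'   pair once).
#' @examples
#' panel <- simulateLDPanel(50, 2, 5, decay = 0.95, seed = 1)
#' panelLdPairs(panel, r2_min = 0.5)
#' @export
panelLdPairs <- function(panel, r2_min = 0.2) {
    stopifnot(is(panel, "LDPanel"))
    H <- panel@haplotypes
    st <- panel@snpTable
    out <- vector("list", length(panel@blockBounds))
    bounds <- c(panel@blockBounds, ncol(H) + 1L)
    for (b in seq_along(panel@blockBounds)) {
        idx <- bounds[b]:(bounds[b + 1L] - 1L)
        if (length(idx) < 2L) next
        r2 <- suppressWarnings(cor(H[, idx, drop = FALSE])^2)
        ut <- which(upper.tri(r2) & r2 > r2_min, arr.ind = TRUE)
        if (!nrow(ut)) next
        out[[b]] <- DataFrame(snp_a = st$snp_id[idx[ut[, 1L]]],
                              snp_b = st$snp_id[idx[ut[, 2L]]],
                              r2 = r2[ut])
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out))
        return(DataFrame(snp_a = character(0), snp_b = character(0),
                         r2 = numeric(0)))
    do.call(rbind, out)
}

#' Simulate a genotyped GWAS cohort from the panel's generative process
#'
#' Draws \code{2 * n_gwas} fresh haplotypes from the same block-copy
#' process that produced the panel (same per-SNP mafs, block structure
#' and decay) and pairs them into diploid genotypes. The panel itself
#' stays an independent LD reference for the cohort, as a reference
#' panel is for a real GWAS sample.
#'
#' @param panel an \linkS4class{LDPanel}.
#' @param n_gwas number of diploid individuals.
#' @param seed integer RNG seed.
#' @return n_gwas x M genotype dosage matrix (0/1/2, double).
#' @export
simulateGwasCohort <- function(panel, n_gwas, seed) {
    stopifnot(is(panel, "LDPanel"))
    n_gwas <- .assertCount(n_gwas, "n_gwas", min = 3L)
    set.seed(.assertCount(seed, "seed", min = 0L))
    st <- panel@snpTable
    blockSizes <- as.integer(table(factor(st$block,
                                          levels = unique(st$block))))
    G <- .simGenotypesC(st$maf, blockSizes, panel@decay, n_gwas)
    storage.mode(G) <- "double"
    colnames(G) <- st$snp_id
    G
}

#' Simulate GWAS summary statistics under the stratified LD-score model
#'
#' Genotype-level generation: per-SNP effect variances are
#' \code{sigma2_j = sum_c tau_c * a_c(j)} (negative values clipped to
#' zero with a warning); standardized effects \code{beta_j ~ Normal(0,
#' sigma2_j)}; a cohort of \code{n_gwas} diploid individuals is drawn
#' from the panel's generative process (see [simulateGwasCohort()]); the
#' phenotype is the standardized genetic value plus Gaussian noise
#' scaled so the phenotypic variance is 1; and each SNP's z score is its
#' marginal regression z statistic. The expected chi-squared then
#' follows \code{E[chi2_j] = 1 + N * sum_c tau_c * l(j,c)} with LD
#' scores computable from the panel.
#'
#' @param panel an \linkS4class{LDPanel}.
#' @param annotations numeric matrix (M SNPs x C annotations) of SNP
#'   annotation values a_c(j); a plain vector is taken as one annotation.
#' @param tau_true per-annotation true coefficients (length C).
#' @param n_gwas GWAS sample size N.
#' @param seed integer RNG seed (governs effects, phenotype noise, and
#'   the cohort when one is not supplied).
#' @param cohort optional genotype matrix from [simulateGwasCohort()],
#'   allowing one genotyped cohort to be reused across phenotype
#'   replicates.
#' @return \code{DataFrame} with columns snp, a1, a2, z, n, chi2; the
#'   planted \code{tau_true} and total h2 are kept in
#'   \code{metadata()$true_tau} / \code{$true_h2}.
#' @examples
#' panel <- simulateLDPanel(100, 5, 20, decay = 0.9, seed = 1)
#' ann <- matrix(1, ncol(haplotypes(panel)), 1)
#' ss <- simulateSumstats(panel, ann, tau_true = 0.2 / 100, n_gwas = 500,
#'     seed = 2)
#' mean(ss$chi2)
#' @export
simulateSumstats <- function(panel, annotations, tau_true, n_gwas, seed,
                             cohort = NULL) {
    stopifnot(is(panel, "LDPanel"))
    M <- ncol(panel@haplotypes)
    ann <- as.matrix(annotations)
    if (nrow(ann) != M)
        stop("annotations must have one row per panel SNP")
    if (length(tau_true) != ncol(ann))
        stop("tau_true must have one value per annotation column")
    n_gwas <- .assertCount(n_gwas, "n_gwas", min = 3L)
    sigma2 <- as.vector(ann %*% tau_true)
    if (any(sigma2 < 0)) {
        warning(sum(sigma2 < 0), " SNPs with negative per-SNP variance ",
                "clipped to 0")
        sigma2 <- pmax(sigma2, 0)
    }
    h2 <- sum(sigma2)
    if (h2 > 1)
        stop("total heritability sum(sigma2) = ", signif(h2, 4),
             " exceeds 1")
    if (is.null(cohort)) {
        cohort <- simulateGwasCohort(panel, n_gwas, seed = seed + 1L)
    } else {
        if (ncol(cohort) != M)
            stop("cohort must cover the panel SNPs")
        if (nrow(cohort) != n_gwas)
            stop("cohort has ", nrow(cohort), " individuals, n_gwas = ",
                 n_gwas)
    }
    set.seed(.assertCount(seed, "seed", min = 0L))
    beta <- rnorm(M, 0, sqrt(sigma2))

    G <- cohort
    n <- n_gwas
    mu <- colMeans(G)
    sdg <- sqrt(pmax(colSums(G^2) - n * mu^2, 0) / (n - 1))
    mono <- sdg == 0
    if (any(mono)) {
        warning(sum(mono), " SNPs monomorphic in the cohort; z set to 0")
        sdg[mono] <- 1
        beta[mono] <- 0
    }
    bs <- beta / sdg
    yg <- as.vector(G %*% bs) - sum(mu * bs)
    varEps <- max(1 - var(yg), 1e-4)
    y <- yg + rnorm(n, 0, sqrt(varEps))

    cross <- as.vector(crossprod(G, y))
    r <- (cross - n * mu * mean(y)) / ((n - 1) * sdg * sd(y))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    z <- r * sqrt((n - 2) / (1 - r^2))
    z[mono] <- 0

    st <- panel@snpTable
    out <- DataFrame(snp = st$snp_id, a1 = st$a1, a2 = st$a2,
                     z = z, n = n_gwas, chi2 = z^2)
    metadata(out) <- list(true_tau = tau_true, true_h2 = h2, seed = seed)
    out
}
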