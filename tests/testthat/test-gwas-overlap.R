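test_that("LD expansion follows the strict r2 rule without chaining", {
    ld <- data.frame(snp_a = c("a", "b", "a", "x"),
                     snp_b = c("b", "c", "c", "y"),
                     r2 = c(0.9, 0.9, 0.3, 0.8))
    # chain a-b (0.9), b-c (0.9), a-c (0.3): c is excluded
    out <- expandLD("a", ld)
    expect_setequal(out$snp_id, c("a", "b"))
    expect_equal(out$source_lead[out$snp_id == "b"], "a")
    # partner exactly at the cutoff is excluded (strict >)
    out2 <- expandLD("x", ld, r2_cut = 0.8)
    expect_equal(out2$snp_id, "x")
    # lead missing from the LD table is retained alone with a warning
    expect_warning(out3 <- expandLD("zz", ld), "absent")
    expect_equal(out3$snp_id, "zz")
    expect_true(out3$is_lead)
    # max-r2 lead tagging
    ld2 <- data.frame(snp_a = c("l1", "l2"), snp_b = c("s", "s"),
                      r2 = c(0.85, 0.95))
    out4 <- expandLD(c("l1", "l2"), ld2)
    expect_equal(out4$source_lead[out4$snp_id == "s"], "l2")
})

# fixture: 4 CREs, 6 links, 5 SNPs with known containment
snpGeneFixture <- function() {
    links <- S4Vectors::DataFrame(
        chrom = "chrT",
        peak_start = c(1000L, 3000L, 5000L, 7000L),
        peak_end = c(1500L, 3500L, 5500L, 7500L),
        peak_id = paste0("p", 1:4),
        gene_id = paste0("g", 1:4),
        is_cre = c(TRUE, TRUE, TRUE, FALSE))
    # peak p1 also linked to g2, p2 also to g3
    links <- rbind(links,
        S4Vectors::DataFrame(chrom = "chrT", peak_start = 1000L,
            peak_end = 1500L, peak_id = "p1", gene_id = "g2",
            is_cre = TRUE),
        S4Vectors::DataFrame(chrom = "chrT", peak_start = 3000L,
            peak_end = 3500L, peak_id = "p2", gene_id = "g3",
            is_cre = TRUE))
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(1201, 20001, 40001, 7100), width = 1))
    names(tss) <- paste0("g", 1:4)
    # SNP positions are 1-based; peak intervals 0-based half-open
    snps <- data.frame(
        snp_id = c("s_in1", "s_start", "s_end", "s_out", "s_in2"),
        chrom = "chrT",
        pos = c(1200L,   # inside p1
                3001L,   # 0-based 3000 = start of p2: contained
                1501L,   # 0-based 1500 = end of p1: NOT contained
                6000L,   # in no peak
                7200L))  # inside p4 (not a CRE)
    list(links = links, tss = tss, snps = snps)
}

test_that("containment uses the half-open convention", {
    fx <- snpGeneFixture()
    mp <- mapSnpsToGenes(fx$snps, fx$links, fx$tss)
    inSnps <- unique(mp$pairs$snp_id)
    expect_true("s_start" %in% inSnps)
    expect_false("s_end" %in% inSnps)
    expect_false("s_out" %in% inSnps)
    # p4 is not a CRE
    expect_false("s_in2" %in% inSnps)
})

test_that("pairs expand over all linked genes and summaries match hand counts", {
    fx <- snpGeneFixture()
    eq <- data.frame(snp_id = c("s_in1", "s_start"),
                     gene_id = c("g1", "g9"))
    mp <- mapSnpsToGenes(fx$snps, fx$links, fx$tss, eqtl = eq)
    # s_in1 in p1 -> g1, g2; s_start in p2 -> g2, g3 : 4 pairs
    expect_equal(mp$summary$n_pairs, 4L)
    expect_equal(mp$summary$n_snps_in_cres, 2L)
    expect_equal(mp$summary$n_genes, 3L)
    # distances: s_in1 (pos0 1199) to g1 tss0 1200 -> 1; to g2 tss0 20000
    d <- mp$pairs$distance_bp[mp$pairs$snp_id == "s_in1"]
    expect_setequal(d, c(1, 18801))
    # distances 1, 18801, 17000, 37000 -> 3 of 4 pairs beyond 10 kb
    expect_equal(mp$summary$frac_pairs_gt10kb, 0.75)
    expect_equal(mp$summary$median_distance_bp, (17000 + 18801) / 2)
    # nearest gene: g1 is nearest to s_in1; g1 also nearest to s_start
    nst <- mp$pairs$is_nearest_gene
    expect_equal(sum(nst), 1L)
    # both CRE SNPs are eQTL SNPs -> 100%; 1 of 4 pairs concordant
    expect_equal(mp$summary$pct_cre_snps_eqtl, 100)
    expect_equal(mp$summary$frac_pairs_eqtl_concordant, 0.25)
})

test_that("mapping is idempotent and order-invariant", {
    fx <- snpGeneFixture()
    mp1 <- mapSnpsToGenes(fx$snps, fx$links, fx$tss)
    mp2 <- mapSnpsToGenes(fx$snps[c(4, 2, 5, 1, 3), ], fx$links, fx$tss)
    expect_identical(as.data.frame(mp1$pairs), as.data.frame(mp2$pairs))
    mp3 <- mapSnpsToGenes(fx$snps, fx$links[sample(nrow(fx$links)), ],
                          fx$tss)
    expect_identical(as.data.frame(mp1$pairs), as.data.frame(mp3$pairs))
})

test_that("permutation p respects the add-one bounds", {
    set.seed(41)
    nP <- 300
    peaks <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(seq(1, by = 1000, length.out = nP), width = 500))
    names(peaks) <- sprintf("p%03d", seq_len(nP))
    feats <- S4Vectors::DataFrame(peak_id = names(peaks),
                                  gc = runif(nP, 0.3, 0.7),
                                  mean_access = rexp(nP))
    cre <- names(peaks)[1:30]
    # all SNPs inside CREs: observed beats every permutation
    snps <- data.frame(snp_id = sprintf("s%02d", 1:20), chrom = "chrT",
                       pos = GenomicRanges::start(peaks)[1:20] + 10L)
    pe <- permutationEnrichment(snps, cre, peaks, feats, n_perm = 200,
                                pool_k = 30, seed = 1)
    expect_equal(pe$observed, 20L)
    expect_equal(pe$p_emp, 1 / 201)
    expect_gte(min(pe$p_emp), 1 / 201)
    expect_length(pe$null, 200)
    # error when the matching pool cannot be built
    expect_error(permutationEnrichment(snps, names(peaks)[1:295], peaks,
                                       feats, n_perm = 10, pool_k = 30,
                                       seed = 1),
                 "non-CRE")
})

test_that("planted SNP placement enriches CRE overlap", {
    set.seed(43)
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 50, n_genes = 30, n_peaks = 400, genome_span = 8e6,
        seed = 47))
    peaks <- peakRanges(sim$multiome)
    feats <- peakFeatures(sim$multiome)
    cre <- names(peaks)[sample(length(peaks), 40)]
    pos <- placeSnps(sprintf("r%03d", 1:200), peaks, frac_in_peaks = 1,
                     cre_peaks = cre, enrichment = 3, seed = 2)
    pe <- permutationEnrichment(pos, cre, peaks, feats, n_perm = 300,
                                pool_k = 50, seed = 3)
    expect_lt(pe$p_emp, 0.05)
    expect_gt(pe$observed, mean(pe$null))
})
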