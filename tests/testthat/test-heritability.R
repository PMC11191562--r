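test_that("differential statistics behave on null and planted data", {
    set.seed(51)
    rna <- matrix(rpois(40 * 60, 5), 40, 60,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("c%02d", 1:60)))
    rnaN <- normalizeCounts(rna)
    lab <- rep(c("A", "B"), each = 30)
    # identical distributions: nothing significant
    de0 <- differentialStats(rnaN, lab, c("A", "B"))
    expect_true(all(de0$fdr >= 0.05 | abs(de0$log2fc) < 1))
    expect_gt(min(de0$p), 0)
    # one gene 10x in group A has the smallest p
    rna2 <- rna
    rna2["g05", lab == "A"] <- rna2["g05", lab == "A"] * 10L
    de1 <- differentialStats(normalizeCounts(rna2), lab, c("A", "B"))
    expect_equal(de1$gene[which.min(de1$p)], "g05")
    expect_gt(de1$log2fc[de1$gene == "g05"], 1)
    # tiny groups rejected
    expect_error(differentialStats(rnaN, rep(c("A", "B"), c(2, 58)),
                                   c("A", "B")), "at least 3")
})

test_that("planted subpopulation markers are recovered", {
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 400, n_genes = 80, n_peaks = 200, n_subpops = 2,
        n_markers_per_subpop = 8, genome_span = 4e6, seed = 53))
    mm <- sim$multiome
    rnaN <- normalizeCounts(rnaCounts(mm))
    mk <- sim$truth$marker_genes
    de <- differentialStats(rnaN, cellInfo(mm)$subpop,
                            c("subpop1", "subpop2"))
    m1 <- mk$gene[mk$subpop == "subpop1"]
    hit <- de$fdr[match(m1, de$gene)] < 0.05 &
        de$log2fc[match(m1, de$gene)] > 1
    expect_gte(mean(hit), 0.75)
})

test_that("gene program weights follow the capped -log10 FDR rule", {
    de <- S4Vectors::DataFrame(gene = c("a", "b", "c", "d"),
                               log2fc = c(2, 1, -2, 1),
                               p = c(1e-12, 1e-5, 1e-9, 0.9),
                               fdr = c(1e-10, 1e-5, 1e-9, 1))
    w <- buildGeneProgram(de, cap = 10)
    expect_equal(unname(w["a"]), 1)      # fdr == 10^-cap saturates
    expect_equal(unname(w["b"]), 0.5)    # -log10(1e-5)/10
    expect_equal(unname(w["c"]), 0)      # downregulated
    expect_equal(unname(w["d"]), 0)      # fdr = 1
    b <- buildGeneProgram(de, mode = "binary")
    expect_equal(unname(b), c(1, 1, 0, 0))
    expect_error(buildGeneProgram(de[3:4, ]), "no positive weights")
})

test_that("program-to-annotation takes the max weight per SNP", {
    links <- S4Vectors::DataFrame(
        chrom = "chrT",
        peak_start = c(100L, 150L, 500L),
        peak_end = c(200L, 250L, 600L),
        peak_id = c("p1", "p2", "p3"),
        gene_id = c("gA", "gB", "gB"),
        is_cre = TRUE)
    prog <- c(gA = 0.3, gB = 0.9, gC = 0.5)
    snps <- data.frame(snp_id = c("s1", "s2", "s3"),
                       chrom = "chrT",
                       pos = c(180L,  # in p1 and p2: max(0.3, 0.9)
                               550L,  # in p3 only: 0.9
                               400L)) # nowhere: 0
    expect_message(a <- programToAnnotation(prog, links, snps),
                   "without CREs")
    expect_equal(unname(a), c(0.9, 0.9, 0))
    # all weights 1 reduces to the binary overlap indicator
    a1 <- suppressMessages(programToAnnotation(
        c(gA = 1, gB = 1), links, snps))
    expect_equal(unname(a1), c(1, 1, 0))
    # direct assignment for a single-gene program
    a2 <- suppressMessages(programToAnnotation(c(gA = 0.7), links, snps))
    expect_equal(unname(a2), c(0.7, 0, 0))
    # namespace mismatch
    snpsX <- transform(snps, chrom = "chrZ")
    expect_error(programToAnnotation(prog, links, snpsX), "mismatch")
})

test_that("LD scores match hand arithmetic on a 4-haplotype fixture", {
    H <- matrix(c(0L, 0L, 1L, 1L,
                  0L, 1L, 1L, 0L), 4, 2)
    p <- manualPanel(H)
    # r = 0 between the SNPs; self r2adj = 1; cross r2adj = 0 - 1/2
    l <- computeLdScores(p, matrix(1, 2, 1), window_bp = 1e4)
    expect_equal(unname(l[, 1]), c(0.5, 0.5))
    # perfectly correlated pair
    H2 <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), 4, 2)
    l2 <- computeLdScores(manualPanel(H2), matrix(1, 2, 1),
                          window_bp = 1e4)
    expect_equal(unname(l2[, 1]), c(2, 2))
    # annotation linearity: doubling a doubles l
    p3 <- simulateLDPanel(50, 3, 10, decay = 0.8, seed = 55)
    a <- matrix(runif(30), 30, 1)
    expect_equal(computeLdScores(p3, 2 * a, 5e3),
                 2 * computeLdScores(p3, a, 5e3), tolerance = 1e-12)
})

test_that("vectorized LD scores equal the brute-force double loop", {
    p <- simulateLDPanel(60, 6, 25, decay = 0.85, seed = 57)
    set.seed(58)
    ann <- cbind(base = rep(1, 150), w = runif(150))
    l <- computeLdScores(p, ann, window_bp = 3e4)
    lb <- bruteLdScores(p, ann, window_bp = 3e4)
    expect_lt(max(abs(l - lb)), 1e-10)
})

test_that("near-independent panel gives base LD scores near 1", {
    p <- simulateLDPanel(400, 1, 60, decay = 0, seed = 59)
    l <- computeLdScores(p, matrix(1, 60, 1), window_bp = 1e6)
    expect_lt(abs(mean(l) - 1), 0.1)
})

test_that("S-LDSC base enrichment is exactly 1 and guards fire", {
    p <- simulateLDPanel(100, 20, 25, decay = 0.9, seed = 61)
    M <- 500
    set.seed(62)
    targ <- sample(rep(c(1, 0), c(100, 400)))
    ann <- cbind(base = rep(1, M), targ = targ)
    tau <- c(0.1 / M, 0.1 / 100)
    ss <- simulateSumstats(p, ann, tau, n_gwas = 2000, seed = 63)
    ld <- computeLdScores(p, ann, window_bp = 5e4)
    fit <- fitSldsc(ss, ld, ann, n_blocks = 20)
    co <- sldscCoefs(fit)
    expect_equal(co$enrichment[co$annotation == "base"], 1,
                 tolerance = 1e-10)
    expect_true(all(co$se_tau > 0))
    expect_true(is.na(co$tau_star[co$annotation == "base"]))  # sd(a)=0
    expect_s4_class(fit, "SldscFit")
    expect_output(show(fit), "intercept")
    # duplicated annotation is rejected as collinear
    ann2 <- cbind(ann, dup = targ)
    ld2 <- computeLdScores(p, ann2, window_bp = 5e4)
    expect_error(fitSldsc(ss, ld2, ann2, n_blocks = 20), "collinear")
})

test_that("conditional tau* absorbs self-conditioning and rejects duplicates", {
    p <- simulateLDPanel(100, 20, 25, decay = 0.9, seed = 65)
    M <- 500
    set.seed(66)
    support <- as.numeric(runif(M) < 0.15)
    progW <- support * runif(M, 0.5, 1)   # weighted program on the support
    annT <- cbind(base = rep(1, M), bg = support)
    tau <- c(0.05 / M, 0.2 / sum(support))
    ss <- simulateSumstats(p, annT, tau, n_gwas = 4000, seed = 67)
    # the true signal follows the binary support: conditioned on that
    # support as background, the weighted program adds nothing
    res <- conditionalTauStar(ss, p, list(progA = progW),
                              background = support, window_bp = 5e4,
                              n_blocks = 20)
    ts <- res$tau_star$tau_star
    se <- res$tau_star$se_tau_star
    expect_lt(abs(ts), 3 * se)
    # two identical program annotations are rejected
    expect_error(conditionalTauStar(ss, p,
                                    list(progA = progW, progB = progW),
                                    window_bp = 5e4, n_blocks = 20),
                 "collinear")
})
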