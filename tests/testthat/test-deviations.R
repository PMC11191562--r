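# 4 peaks x 3 cells toy used for the arithmetic oracle
toyAtac <- function() {
    matrix(c(1, 2, 3,
             2, 2, 2,
             0, 1, 4,
             3, 0, 1), nrow = 4, byrow = TRUE,
           dimnames = list(paste0("p", 1:4), paste0("c", 1:3)))
}
toyFeatures <- function() {
    S4Vectors::DataFrame(peak_id = paste0("p", 1:4),
                         gc = c(0.4, 0.45, 0.5, 0.55),
                         mean_access = c(2, 2, 5 / 3, 4 / 3))
}

test_that("raw deviations equal (obs - exp)/exp on the toy", {
    dev <- computeDeviations(toyAtac(),
        data.frame(tf = "tfA", peak_id = c("p1", "p2")),
        features = toyFeatures(), n_bg = 5, pool_k = 2, seed = 1)
    # hand arithmetic: obs = (3,4,5); exp = 12/21 * (6,5,10)
    expect_equal(unname(deviationScores(dev, "raw")["tfA", ]),
                 c(-0.125, 0.4, -0.125), tolerance = 1e-12)
})

test_that("cells proportional to the mean profile have zero deviation", {
    prof <- c(4, 3, 2, 1)
    atac <- outer(prof, c(1, 2, 5))
    dimnames(atac) <- list(paste0("p", 1:4), paste0("c", 1:3))
    dev <- computeDeviations(atac,
        data.frame(tf = c("a", "a", "b"), peak_id = c("p1", "p3", "p2")),
        features = toyFeatures(), n_bg = 5, pool_k = 2, seed = 1)
    expect_equal(max(abs(deviationScores(dev, "raw"))), 0,
                 tolerance = 1e-12)
})

test_that("a motif covering all peaks has zero deviation (expectation is exact)", {
    dev <- computeDeviations(toyAtac(),
        data.frame(tf = "all", peak_id = paste0("p", 1:4)),
        features = toyFeatures(), n_bg = 5, pool_k = 2, seed = 1)
    expect_equal(max(abs(deviationScores(dev, "raw"))), 0,
                 tolerance = 1e-12)
})

test_that("deviations are invariant to scaling all counts", {
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 120, n_genes = 40, n_peaks = 200, n_tfs = 5,
        genome_span = 4e6, seed = 13))
    mm <- sim$multiome
    feats <- peakFeatures(mm)
    d1 <- computeDeviations(atacCounts(mm), sim$truth$motif_hits,
                            features = feats, n_bg = 10, seed = 2)
    d3 <- computeDeviations(atacCounts(mm) * 3, sim$truth$motif_hits,
                            features = feats, n_bg = 10, seed = 2)
    expect_lt(max(abs(deviationScores(d1) - deviationScores(d3))), 0.1)
})

test_that("a TF with zero expected accessibility is an error", {
    atac <- toyAtac()
    atac["p1", ] <- 0
    expect_error(computeDeviations(atac,
        data.frame(tf = "dead", peak_id = "p1"),
        features = toyFeatures(), n_bg = 5, pool_k = 2, seed = 1),
        "dead")
})

test_that("deviation z is near standard normal when peaks are exchangeable", {
    # no motif effect and no subpopulation structure: every peak set is
    # exchangeable with its matched background
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 300, n_genes = 40, n_peaks = 500, n_tfs = 8,
        n_subpops = 1, motif_effect = 0, genome_span = 1e7, seed = 17))
    dev <- computeDeviations(sim$multiome, sim$truth$motif_hits,
                             n_bg = 50, seed = 3)
    z <- deviationScores(dev)
    expect_lt(abs(mean(z)), 0.15)
    expect_gt(sd(z), 0.75)
    expect_lt(sd(z), 1.35)
})

test_that("planted activators and repressors are classified by sign", {
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 400, n_genes = 60, n_peaks = 500, n_tfs = 8,
        motif_effect = 0.8, genome_span = 1e7, seed = 19))
    dev <- computeDeviations(sim$multiome, sim$truth$motif_hits,
                             n_bg = 30, seed = 4)
    rnaN <- normalizeCounts(rnaCounts(sim$multiome))
    tab <- deviationExpressionCorrelation(dev, rnaN)
    sign_truth <- sim$truth$tf_sign[tab$tf]
    expected <- ifelse(sign_truth > 0, "positive", "negative")
    expect_gte(mean(tab$class == expected), 0.75)
    # shuffled expression breaks the association
    set.seed(5)
    rnaS <- as.matrix(rnaN)[, sample(ncol(rnaN))]
    colnames(rnaS) <- colnames(rnaN)
    tabS <- deviationExpressionCorrelation(dev, rnaS)
    expect_gte(mean(tabS$class == "ns"), 0.8)
})
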