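# compact TF-DORC scoring fixture
figrFixture <- function(n_tfs = 6, n_dorcs = 4, n_cells = 40,
                        n_peaks = 120, seed = 31) {
    set.seed(seed)
    peaks <- sprintf("p%03d", seq_len(n_peaks))
    feats <- S4Vectors::DataFrame(peak_id = peaks,
                                  gc = runif(n_peaks, 0.3, 0.7),
                                  mean_access = rexp(n_peaks))
    dorcGenes <- sprintf("d%02d", seq_len(n_dorcs))
    sets <- split(sample(peaks, 3 * n_dorcs),
                  rep(seq_len(n_dorcs), each = 3))
    dorcs <- S4Vectors::DataFrame(gene_id = dorcGenes, n_cres = 3L,
                                  cre_peak_ids = I(unname(sets)))
    tfs <- sprintf("tf%02d", seq_len(n_tfs))
    hits <- data.frame(
        tf = rep(tfs, each = 20),
        peak_id = unlist(lapply(seq_len(n_tfs),
                                function(i) sample(peaks, 20))))
    rna <- matrix(rnorm(n_tfs * n_cells), n_tfs, n_cells,
                  dimnames = list(tfs, paste0("c", seq_len(n_cells))))
    sc <- matrix(rexp(n_dorcs * n_cells), n_dorcs, n_cells,
                 dimnames = list(dorcGenes, colnames(rna)))
    list(dorcs = dorcs, sc = sc, rna = rna, hits = hits, feats = feats)
}

test_that("all TF x DORC pairs are enumerated", {
    fx <- figrFixture()
    ed <- scoreTfDorc(fx$dorcs, fx$sc, fx$rna, fx$hits, fx$feats,
                      n_bg = 5, pool_k = 10, seed = 1)
    expect_equal(nrow(ed), 6 * 4)
    expect_equal(length(unique(ed$tf)), 6)
    expect_equal(length(unique(ed$dorc)), 4)
    expect_true(all(ed$p_enrich > 0 & ed$p_enrich <= 1))
    expect_true(all(ed$p_corr > 0 & ed$p_corr <= 1))
    # sign(reg_score) follows sign(rho) when nonzero
    nz <- ed$reg_score != 0
    expect_equal(sign(ed$reg_score[nz]), sign(ed$rho[nz]))
})

test_that("a TF without motif hits in the universe scores zero", {
    fx <- figrFixture()
    rna <- rbind(fx$rna, tf99 = rnorm(ncol(fx$rna)))
    # tf99 has a single hit outside every CRE set: enrichment can never
    # exceed background
    free <- setdiff(fx$feats$peak_id, unlist(fx$dorcs$cre_peak_ids))
    hits <- rbind(fx$hits, data.frame(tf = "tf99", peak_id = free[1]))
    ed <- scoreTfDorc(fx$dorcs, fx$sc, rna, hits, fx$feats,
                      n_bg = 5, pool_k = 10, seed = 1)
    sub <- ed[ed$tf == "tf99", ]
    # observed hit count in every DORC CRE set is 0
    expect_true(all(sub$obs_hits == 0))
    expect_true(all(abs(sub$reg_score) <= -log10(0.5) + 1e-9))
})

test_that("reg_score is antisymmetric under negating TF expression", {
    fx <- figrFixture()
    e1 <- scoreTfDorc(fx$dorcs, fx$sc, fx$rna, fx$hits, fx$feats,
                      n_bg = 5, pool_k = 10, seed = 1)
    e2 <- scoreTfDorc(fx$dorcs, fx$sc, -fx$rna, fx$hits, fx$feats,
                      n_bg = 5, pool_k = 10, seed = 1)
    expect_equal(e1$rho, -e2$rho, tolerance = 1e-12)
    expect_equal(e1$p_corr, e2$p_corr, tolerance = 1e-12)
    expect_equal(e1$reg_score, -e2$reg_score, tolerance = 1e-12)
})

test_that("network thresholding filters and counts edges", {
    ed <- S4Vectors::DataFrame(tf = c("a", "b", "c"),
                               dorc = c("g1", "g2", "g3"),
                               reg_score = c(-2.0, 1.4, 1.6))
    net <- buildNetwork(ed, threshold = 1.5)
    expect_equal(net$n_edges, 2L)
    expect_equal(net$n_repressive, 1L)
    expect_equal(net$n_activating, 1L)
    expect_equal(sort(net$edges$source), c("a", "c"))
    # threshold = Inf empties the network; 0 keeps all nonzero
    expect_equal(buildNetwork(ed, Inf)$n_edges, 0L)
    expect_equal(buildNetwork(ed, 0)$n_edges, 3L)
    # monotone non-increasing in threshold
    counts <- vapply(c(0, 1, 1.5, 1.9, 2.5),
                     function(t) buildNetwork(ed, t)$n_edges, 1L)
    expect_true(all(diff(counts) <= 0))
})

test_that("the planted TF-driven program ranks in the top edge decile", {
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 500, n_genes = 80, n_peaks = 600, n_tfs = 6,
        n_subpops = 1, motif_effect = 1.2, frac_linked_peaks = 0.08,
        links_per_gene = 10, genome_span = 1.2e7, seed = 37))
    mm <- sim$multiome
    prog <- sim$truth$tf_program
    expect_false(is.null(prog))
    links <- linkPeaksToGenes(mm, n_bg = 50)
    dorcs <- callDorcs(links, min_cres = 3)
    expect_true(prog$gene %in% dorcs$gene_id)
    sc <- dorcScores(mm, dorcs)
    rnaN <- normalizeCounts(rnaCounts(mm))
    ed <- scoreTfDorc(dorcs, sc, rnaN, sim$truth$motif_hits,
                      peakFeatures(mm), n_bg = 25, seed = 7)
    scores <- abs(ed$reg_score)
    planted <- scores[ed$tf == prog$tf & ed$dorc == prog$gene]
    expect_gte(planted, quantile(scores, 0.9, na.rm = TRUE))
})
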