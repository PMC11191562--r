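test_that("windowed correlations equal a brute-force all-pairs oracle", {
    mm <- tinyMultiome()
    links <- linkPeaksToGenes(mm, window_bp = 5e5, n_bg = 10)
    expect_gt(nrow(links), 0)
    rnaN <- as.matrix(normalizeCounts(rnaCounts(mm)))
    atacN <- as.matrix(normalizeCounts(atacCounts(mm)))
    for (i in seq_len(nrow(links))) {
        r <- cor(atacN[links$peak_id[i], ], rnaN[links$gene_id[i], ])
        expect_equal(links$r_obs[i], r, tolerance = 1e-12)
    }
    # every tested pair is inside the window, strict inequality
    expect_true(all(abs(links$distance_bp) < 5e5))
})

test_that("pair enumeration matches the window definition", {
    mm <- tinyMultiome()
    links <- linkPeaksToGenes(mm, window_bp = 3e5, n_bg = 10)
    pk <- peakRanges(mm); ts <- tssRanges(mm)
    mid0 <- GenomicRanges::start(pk) - 1 + GenomicRanges::width(pk) / 2
    tss0 <- GenomicRanges::start(ts) - 1
    manual <- expand.grid(p = seq_along(pk), g = seq_along(ts))
    manual <- manual[abs(mid0[manual$p] - tss0[manual$g]) < 3e5, ]
    expect_equal(nrow(links), nrow(manual))
    # a gene with no peak within the window is absent
    far <- names(ts)[!names(ts) %in% links$gene_id]
    for (g in far) {
        gi <- match(g, names(ts))
        expect_true(all(abs(mid0 - tss0[gi]) >= 3e5))
    }
})

test_that("link table is invariant to cell order", {
    mm <- tinyMultiome()
    set.seed(3)
    perm <- sample(nCells(mm))
    mm2 <- Multiome(rnaCounts(mm)[, perm], atacCounts(mm)[, perm],
                    peakRanges(mm), tssRanges(mm), cellInfo(mm)[perm, ])
    l1 <- linkPeaksToGenes(mm, n_bg = 10)
    l2 <- linkPeaksToGenes(mm2, n_bg = 10)
    expect_identical(l1$peak_id, l2$peak_id)
    expect_identical(l1$gene_id, l2$gene_id)
    expect_equal(l1$r_obs, l2$r_obs, tolerance = 1e-10)
    expect_equal(l1$z_link, l2$z_link, tolerance = 1e-8)
    expect_identical(l1$is_cre, l2$is_cre)
})

test_that("DORC calling applies the CRE-density threshold exactly", {
    links <- S4Vectors::DataFrame(
        peak_id = paste0("p", 1:20),
        gene_id = rep(c("g1", "g2", "g3"), c(9, 8, 3)),
        is_cre = TRUE)
    d9 <- callDorcs(links, min_cres = 9)
    expect_equal(d9$gene_id, "g1")
    expect_equal(d9$n_cres, 9L)
    # boundary: 8 CREs excluded at threshold 9
    expect_false("g2" %in% d9$gene_id)
    # empty input
    expect_equal(nrow(callDorcs(links[0, ], 9)), 0L)
    # non-CRE rows never count
    links$is_cre[1:9] <- FALSE
    expect_equal(nrow(callDorcs(links, 9)), 0L)
})

test_that("DORC scores are sums of normalized accessibility", {
    counts <- matrix(c(4, 0, 1,
                       2, 0, 3,
                       0, 0, 2,
                       2, 4, 2), nrow = 4, byrow = TRUE,
                     dimnames = list(paste0("p", 1:4), paste0("c", 1:3)))
    gr <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(1, 1000, 2000, 3000), width = 500))
    names(gr) <- rownames(counts)
    S4Vectors::mcols(gr)$gc <- rep(0.5, 4)
    rna <- matrix(1, 2, 3, dimnames = list(c("g1", "g2"), colnames(counts)))
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = c(1, 5), width = 1))
    names(tss) <- c("g1", "g2")
    mm <- Multiome(rna, counts, gr, tss,
                   S4Vectors::DataFrame(subpop = "s",
                       treatment = c("oxldl", "unexposed", "oxldl"),
                       row.names = colnames(counts)))
    dorcs <- S4Vectors::DataFrame(gene_id = "g1", n_cres = 3L,
        cre_peak_ids = I(list(c("p1", "p2", "p4"))))
    sc <- dorcScores(mm, dorcs, scale = 10)
    aN <- log1p(sweep(counts, 2, colSums(counts), "/") * 10)
    expect_equal(sc["g1", ], colSums(aN[c("p1", "p2", "p4"), ]))
    # cell with zero counts at all of a DORC's CREs scores 0
    d2 <- S4Vectors::DataFrame(gene_id = "g2", n_cres = 2L,
        cre_peak_ids = I(list(c("p1", "p2"))))
    expect_equal(unname(dorcScores(mm, d2, scale = 10)["g2", "c2"]), 0)
    # missing peak fails
    bad <- S4Vectors::DataFrame(gene_id = "g1", n_cres = 1L,
        cre_peak_ids = I(list("p9")))
    expect_error(dorcScores(mm, bad), "missing peak")
})

test_that("delta-response correlation is 1 when deltas coincide", {
    # rna rows equal atac rows, one CRE per gene -> identical deltas
    set.seed(8)
    counts <- matrix(rpois(5 * 20, 6), 5, 20,
                     dimnames = list(paste0("p", 1:5), paste0("c", 1:20)))
    rna <- counts
    rownames(rna) <- paste0("g", 1:5)
    gr <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(seq(1, by = 1000, length.out = 5), width = 500))
    names(gr) <- rownames(counts)
    S4Vectors::mcols(gr)$gc <- rep(0.5, 5)
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = seq(1, by = 1000, length.out = 5),
                         width = 1))
    names(tss) <- rownames(rna)
    mm <- Multiome(rna, counts, gr, tss,
                   S4Vectors::DataFrame(subpop = "s",
                       treatment = rep(c("oxldl", "unexposed"), 10),
                       row.names = colnames(counts)))
    dorcs <- S4Vectors::DataFrame(gene_id = paste0("g", 1:5), n_cres = 1L,
        cre_peak_ids = I(as.list(paste0("p", 1:5))))
    dc <- deltaResponseCorrelation(mm, dorcs)
    expect_equal(dc$r, 1, tolerance = 1e-12)
    expect_equal(dc$per_gene$delta_access, dc$per_gene$delta_expr)
    # fewer than 3 DORC genes fails
    expect_error(deltaResponseCorrelation(mm, dorcs[1:2, ]), "at least 3")
})

test_that("treatment acting through linked peaks yields positive delta R", {
    sim <- simulateMultiome(simMultiomeConfig(
        n_cells = 600, n_genes = 80, n_peaks = 600, genome_span = 1.2e7,
        n_subpops = 1, frac_linked_peaks = 0.1, links_per_gene = 8,
        n_response_genes = 10, seed = 21))
    links <- linkPeaksToGenes(sim$multiome, n_bg = 50)
    dorcs <- callDorcs(links, min_cres = 2)
    expect_gte(nrow(dorcs), 3)
    dc <- deltaResponseCorrelation(sim$multiome, dorcs)
    expect_gt(dc$r, 0.3)
    expect_lt(dc$p, 0.05)
    # shuffled treatment labels remove the response signal: the deltas
    # collapse to the sampling-noise scale (their correlation persists
    # through the per-cell chromatin-expression coupling, so the
    # magnitude, not R, carries the permutation null)
    set.seed(4)
    mags <- replicate(6, {
        cd <- cellInfo(sim$multiome)
        cd$treatment <- sample(cd$treatment)
        mm2 <- Multiome(rnaCounts(sim$multiome), atacCounts(sim$multiome),
                        peakRanges(sim$multiome), tssRanges(sim$multiome),
                        cd)
        dcS <- deltaResponseCorrelation(mm2, dorcs)
        mean(abs(dcS$per_gene$delta_expr))
    })
    expect_lt(mean(mags), 0.3 * mean(abs(dc$per_gene$delta_expr)))
})
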