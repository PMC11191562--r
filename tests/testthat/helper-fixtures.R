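# Shared fixtures, built in code.

# tiny deterministic Multiome with explicit coordinates for hand oracles
tinyMultiome <- function(seed = 42, n_cells = 50, n_genes = 20,
                         n_peaks = 60, span = 4e6) {
    set.seed(seed)
    genes <- sprintf("g%02d", seq_len(n_genes))
    peaks <- sprintf("p%02d", seq_len(n_peaks))
    cells <- sprintf("c%02d", seq_len(n_cells))
    rna <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
                  dimnames = list(genes, cells))
    atac <- matrix(rpois(n_peaks * n_cells, 3), n_peaks, n_cells,
                   dimnames = list(peaks, cells))
    pkStart <- sort(sample.int(span - 600L, n_peaks))
    gr <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = pkStart + 1L, width = 500L))
    names(gr) <- peaks
    S4Vectors::mcols(gr)$gc <- runif(n_peaks, 0.3, 0.7)
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = sort(sample.int(span, n_genes)) + 1L,
                         width = 1L),
        strand = sample(c("+", "-"), n_genes, replace = TRUE))
    names(tss) <- genes
    cd <- S4Vectors::DataFrame(
        subpop = sample(c("subpop1", "subpop2"), n_cells, replace = TRUE),
        treatment = sample(c("unexposed", "oxldl"), n_cells,
                           replace = TRUE),
        row.names = cells)
    Multiome(rna, atac, gr, tss, cd)
}

# LDPanel with explicit haplotypes for arithmetic oracles
manualPanel <- function(H, pos = NULL, block = NULL, decay = 0) {
    M <- ncol(H)
    if (is.null(pos)) pos <- seq_len(M) * 1000L
    if (is.null(block)) block <- rep(1L, M)
    freq <- colMeans(H)
    maf <- pmin(pmax(pmin(freq, 1 - freq), 0.05), 0.5)
    st <- S4Vectors::DataFrame(
        snp_id = sprintf("s%03d", seq_len(M)), chrom = "chrG",
        pos = as.integer(pos), a1 = rep("A", M), a2 = rep("G", M),
        maf = maf, block = as.integer(block))
    colnames(H) <- st$snp_id
    new("LDPanel", haplotypes = H, snpTable = st,
        blockBounds = as.integer(which(!duplicated(block))),
        decay = decay)
}

# brute-force LD scores: double loop over SNP pairs within the window
bruteLdScores <- function(panel, ann, window_bp) {
    H <- haplotypes(panel)
    n <- nrow(H)
    pos <- snpInfo(panel)$pos
    M <- ncol(H)
    ann <- as.matrix(ann)
    out <- matrix(0, M, ncol(ann))
    for (j in seq_len(M)) {
        for (k in seq_len(M)) {
            if (abs(pos[k] - pos[j]) > window_bp) next
            r2 <- cor(H[, j], H[, k])^2
            r2 <- r2 - (1 - r2) / (n - 2)
            out[j, ] <- out[j, ] + r2 * ann[k, ]
        }
    }
    out
}
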