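# motif hits -> sparse peak x TF indicator
.motifIndicator <- function(motifs, peakIds) {
    if (is(motifs, "DataFrame") || is.data.frame(motifs)) {
        if (!all(c("tf", "peak_id") %in% colnames(motifs)))
            stop("motif hit table needs 'tf' and 'peak_id' columns")
        bad <- setdiff(unique(motifs$peak_id), peakIds)
        if (length(bad))
            stop("motif hits reference unknown peaks: ",
                 paste(head(bad, 3), collapse = ", "))
        tfs <- sort(unique(motifs$tf))
        M <- sparseMatrix(i = match(motifs$peak_id, peakIds),
                          j = match(motifs$tf, tfs), x = 1,
                          dims = c(length(peakIds), length(tfs)),
                          dimnames = list(peakIds, tfs))
        M@x[] <- 1  # collapse duplicate hits
        return(M)
    }
    # matrix input: TF x peak incidence
    m <- as(as(as(Matrix(motifs, sparse = TRUE), "dMatrix"),
               "generalMatrix"), "CsparseMatrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("motif matrix must carry TF rownames and peak colnames")
    if (!all(colnames(m) %in% peakIds))
        stop("motif matrix peaks must be a subset of the ATAC peaks")
    out <- Matrix(0, length(peakIds), nrow(m), sparse = TRUE,
                  dimnames = list(peakIds, rownames(m)))
    out[colnames(m), ] <- t(m)
    as(as(out, "generalMatrix"), "CsparseMatrix")
}

#' chromVAR-style per-cell TF motif deviation scores
#'
#' For TF m with motif peak set S, the raw deviation of cell i is
#' \code{(obs - exp)/exp} where \code{obs} is the cell's total count over
#' S and \code{exp = rowsum_i * sum_{j in S} colsum_j / total} is the
#' expectation under the average accessibility profile. Each of
#' \code{n_bg} background iterations replaces every member of S by one
#' peak drawn uniformly from its \code{pool_k} GC/accessibility-matched
#' peaks; the deviation z score standardizes the raw deviation against
#' the background mean and sd. Deviations are computed on raw counts.
#'
#' @param atac peak x cell count matrix, or a \linkS4class{Multiome}.
#' @param motifs motif hits: \code{DataFrame}/data.frame with columns
#'   \code{tf}, \code{peak_id}, or a TF x peak binary matrix.
#' @param features peak feature table from [peakFeatures()]; required
#'   when \code{atac} is a bare matrix.
#' @param n_bg number of background iterations (default 50).
#' @param pool_k size of each peak's matched candidate pool (default 50).
#' @param seed integer RNG seed for background sampling.
#' @return a \linkS4class{MotifDeviations}.
#' @examples
#' sim <- simulateMultiome(simMultiomeConfig(n_cells = 100, n_genes = 30,
#'     n_peaks = 200, n_tfs = 4, seed = 1))
#' dev <- computeDeviations(sim$multiome, sim$truth$motif_hits,
#'     n_bg = 10, seed = 1)
#' dev
#' @export
computeDeviations <- function(atac, motifs, features = NULL, n_bg = 50,
                              pool_k = 50, seed = 1) {
    if (is(atac, "Multiome")) {
        if (is.null(features)) features <- peakFeatures(atac)
        atac <- atacCounts(atac)
    }
    if (is.null(features))
        stop("'features' is required when 'atac' is a matrix")
    n_bg <- .assertCount(n_bg, "n_bg", min = 2L)
    pool_k <- .assertCount(pool_k, "pool_k")
    if (min(atac) < 0) stop("counts must be non-negative")
    peakIds <- rownames(atac)
    if (is.null(peakIds)) stop("atac must carry peak rownames")
    P <- .motifIndicator(motifs, peakIds)
    tfs <- colnames(P)

    cellSum <- colSums(atac)
    peakSum <- rowSums(atac)
    total <- sum(peakSum)
    fracS <- as.vector(crossprod(P, peakSum)) / total
    if (any(fracS == 0))
        stop("TF(s) with zero expected accessibility: ",
             paste(head(tfs[fracS == 0], 3), collapse = ", "))
    obs <- as.matrix(crossprod(P, atac))              # tf x cell
    expd <- outer(fracS, cellSum)
    raw <- (obs - expd) / expd

    set.seed(.assertCount(seed, "seed", min = 0L))
    pool <- .matchAllPeaks(features, k = pool_k)
    memb <- lapply(seq_along(tfs), function(m) which(P[, m] != 0))
    bgMean <- matrix(0, nrow(raw), ncol(raw))
    bgM2 <- matrix(0, nrow(raw), ncol(raw))
    for (b in seq_len(n_bg)) {
        drawn <- lapply(memb, function(jj)
            pool[cbind(jj, sample.int(pool_k, length(jj), replace = TRUE))])
        Pb <- sparseMatrix(i = unlist(drawn),
                           j = rep(seq_along(tfs), lengths(drawn)),
                           x = 1, dims = dim(P))
        fracB <- as.vector(crossprod(Pb, peakSum)) / total
        fracB[fracB == 0] <- NA_real_
        expB <- outer(fracB, cellSum)
        devB <- (as.matrix(crossprod(Pb, atac)) - expB) / expB
        bgMean <- bgMean + devB
        bgM2 <- bgM2 + devB^2
    }
    bgMean <- bgMean / n_bg
    bgSd <- sqrt(pmax(bgM2 / n_bg - bgMean^2, 0) * n_bg / (n_bg - 1))
    z <- (raw - bgMean) / bgSd
    z[!is.finite(z)] <- 0
    dimnames(raw) <- dimnames(z) <- list(tfs, colnames(atac))
    new("MotifDeviations", raw = raw, z = z)
}

#' Correlate TF motif deviations with TF expression
#'
#' Per TF: the mean deviation z score across cells, the Pearson
#' correlation between the deviation z scores and the TF gene's
#' normalized expression across cells, a BH-FDR across TFs, and a class
#' label: \code{"positive"} / \code{"negative"} when the correlation is
#' significant at \code{fdr_cut} (activator / repressor behaviour),
#' otherwise \code{"ns"}.
#'
#' @param dev a \linkS4class{MotifDeviations}.
#' @param rna normalized gene x cell expression matrix (same cells).
#' @param tf_gene_map named character vector TF -> gene id; by default
#'   TF names are taken to be gene ids.
#' @param fdr_cut significance threshold (default 0.05).
#' @return \code{DataFrame}: tf, mean_dev, pearson_r, p, fdr, class.
#' @export
deviationExpressionCorrelation <- function(dev, rna, tf_gene_map = NULL,
                                           fdr_cut = 0.05) {
    stopifnot(is(dev, "MotifDeviations"))
    z <- deviationScores(dev, "z")
    tfs <- rownames(z)
    if (is.null(tf_gene_map))
        tf_gene_map <- setNames(tfs, tfs)
    genes <- tf_gene_map[tfs]
    miss <- tfs[is.na(genes) | !(genes %in% rownames(rna))]
    if (length(miss))
        stop("TF(s) without an expression gene: ",
             paste(head(miss, 3), collapse = ", "))
    if (ncol(rna) != ncol(z))
        stop("rna and deviations must cover the same cells")
    n <- ncol(z)
    r <- p <- rep(NA_real_, length(tfs))
    for (i in seq_along(tfs)) {
        e <- as.numeric(rna[genes[i], ])
        if (sd(e) == 0 || sd(z[i, ]) == 0) {
            warning("constant expression or deviations for TF ", tfs[i],
                    "; class set to ns")
            next
        }
        r[i] <- cor(z[i, ], e)
        p[i] <- .corTestP(r[i], n)
    }
    fdr <- rep(NA_real_, length(tfs))
    ok <- !is.na(p)
    fdr[ok] <- p.adjust(p[ok], method = "BH")
    cls <- ifelse(!ok | fdr >= fdr_cut, "ns",
                  ifelse(r > 0, "positive", "negative"))
    DataFrame(tf = tfs, gene_id = unname(genes),
              mean_dev = rowMeans(z), pearson_r = r, p = p, fdr = fdr,
              class = cls)
}
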