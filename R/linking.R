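#' Link peaks to genes within a cis window against matched backgrounds
#'
#' For every (peak, gene) pair whose peak midpoint lies within
#' \code{window_bp} of the gene's strand-aware TSS, computes the Pearson
#' correlation between normalized peak accessibility and normalized gene
#' expression across cells, then standardizes it against the correlations
#' of the same gene with \code{n_bg} background peaks matched on GC and
#' mean accessibility ([matchBackgroundPeaks()]). The background z score
#' is converted to a two-sided normal p-value and BH-corrected over all
#' tested pairs. Pairs with \code{fdr < fdr_cut} and positive correlation
#' are flagged as CREs; significant negative correlations stay in the
#' table but are not CREs.
#'
#' Peaks or genes with zero variance across cells, and pairs whose
#' background correlation spread is zero, are skipped with a warning.
#'
#' @param multiome a \linkS4class{Multiome}.
#' @param features optional precomputed [peakFeatures()] table.
#' @param window_bp cis-window radius in bp (default 500000, strict
#'   inequality).
#' @param n_bg number of matched background peaks per tested peak.
#' @param fdr_cut BH-FDR threshold for calling CREs.
#' @param scale normalization scale.
#' @return a \code{LinkTable}: \code{DataFrame} with columns chrom,
#'   peak_start, peak_end (0-based half-open), peak_id, gene_id,
#'   distance_bp (midpoint to TSS, sign follows gene strand), r_obs,
#'   z_link, p_link, fdr, is_cre.
#' @examples
#' sim <- simulateMultiome(simMultiomeConfig(n_cells = 200, n_genes = 40,
#'     n_peaks = 300, genome_span = 5e6, seed = 1))
#' links <- linkPeaksToGenes(sim$multiome, n_bg = 50)
#' head(links)
#' @export
linkPeaksToGenes <- function(multiome, features = NULL, window_bp = 5e5,
                             n_bg = 200, fdr_cut = 0.05, scale = 1e4) {
    stopifnot(is(multiome, "Multiome"))
    .assertPositive(window_bp, "window_bp")
    n_bg <- .assertCount(n_bg, "n_bg", min = 2L)
    if (is.null(features)) features <- peakFeatures(multiome, scale = scale)

    peaks <- peakRanges(multiome)
    tss <- tssRanges(multiome)
    peakIds <- names(peaks)
    geneIds <- names(tss)
    start0 <- start(peaks) - 1
    end0 <- end(peaks)
    mid0 <- start0 + width(peaks) / 2
    tss0 <- start(tss) - 1

    # enumerate in-window pairs per chromosome
    pairPeak <- integer(0); pairGene <- integer(0)
    pchr <- as.character(seqnames(peaks))
    gchr <- as.character(seqnames(tss))
    for (ch in unique(gchr)) {
        pj <- which(pchr == ch)
        if (!length(pj)) next
        ord <- pj[order(mid0[pj])]
        mids <- mid0[ord]
        for (gi in which(gchr == ch)) {
            lo <- findInterval(tss0[gi] - window_bp, mids) + 1L
            hi <- findInterval(tss0[gi] + window_bp, mids)
            if (hi < lo) next
            sel <- ord[lo:hi]
            sel <- sel[abs(mid0[sel] - tss0[gi]) < window_bp]
            if (!length(sel)) next
            pairPeak <- c(pairPeak, sel)
            pairGene <- c(pairGene, rep.int(gi, length(sel)))
        }
    }
    emptyOut <- DataFrame(chrom = character(0), peak_start = integer(0),
                          peak_end = integer(0), peak_id = character(0),
                          gene_id = character(0), distance_bp = numeric(0),
                          r_obs = numeric(0), z_link = numeric(0),
                          p_link = numeric(0), fdr = numeric(0),
                          is_cre = logical(0))
    if (!length(pairPeak)) return(emptyOut)

    atacN <- as.matrix(normalizeCounts(atacCounts(multiome), scale = scale))
    rnaN <- as.matrix(normalizeCounts(rnaCounts(multiome), scale = scale))
    xs <- .rowStandardize(atacN)
    gs <- .rowStandardize(rnaN)
    if (any(xs$constant) || any(gs$constant))
        warning(sum(xs$constant), " constant peaks and ",
                sum(gs$constant), " constant genes skipped")
    keep <- !xs$constant[pairPeak] & !gs$constant[pairGene]
    pairPeak <- pairPeak[keep]; pairGene <- pairGene[keep]
    if (!length(pairPeak)) return(emptyOut)
    nC <- ncol(atacN)
    R <- tcrossprod(xs$mat, gs$mat) / (nC - 1)

    usable <- which(!xs$constant)
    qPeaks <- sort(unique(pairPeak))
    B <- .matchAllPeaks(features, k = n_bg, query = qPeaks,
                        candidates = usable)
    rownames(B) <- as.character(qPeaks)

    rObs <- R[cbind(pairPeak, pairGene)]
    muN <- sdN <- numeric(length(pairPeak))
    for (gi in unique(pairGene)) {
        rows <- which(pairGene == gi)
        Bsub <- B[as.character(pairPeak[rows]), , drop = FALSE]
        nullv <- matrix(R[cbind(as.vector(Bsub), gi)], nrow = length(rows))
        muN[rows] <- rowMeans(nullv)
        sdN[rows] <- .rowSds(nullv)
    }
    degen <- sdN == 0
    if (any(degen))
        warning(sum(degen), " pairs skipped: zero background spread")
    ok <- !degen
    z <- (rObs[ok] - muN[ok]) / sdN[ok]
    p <- 2 * pnorm(-abs(z))
    fdr <- p.adjust(p, method = "BH")

    pk <- pairPeak[ok]; gn <- pairGene[ok]
    sgn <- ifelse(as.character(strand(tss))[gn] == "-", -1, 1)
    out <- DataFrame(
        chrom = pchr[pk],
        peak_start = as.integer(start0[pk]),
        peak_end = as.integer(end0[pk]),
        peak_id = peakIds[pk],
        gene_id = geneIds[gn],
        distance_bp = (mid0[pk] - tss0[gn]) * sgn,
        r_obs = rObs[ok],
        z_link = z,
        p_link = p,
        fdr = fdr,
        is_cre = fdr < fdr_cut & rObs[ok] > 0)
    metadata(out) <- list(window_bp = window_bp, n_bg = n_bg,
                          fdr_cut = fdr_cut, n_tested = length(z))
    out
}

#' Call domains of regulatory chromatin (DORCs)
#'
#' Genes whose number of CREs meets the density threshold (>= 9 by
#' default) are DORC genes.
#'
#' @param links a LinkTable from [linkPeaksToGenes()].
#' @param min_cres minimum number of CREs per gene (default 9).
#' @return \code{DataFrame} with gene_id, n_cres, and cre_peak_ids (a
#'   CharacterList of the gene's CRE peaks), sorted by descending n_cres.
#' @examples
#' links <- S4Vectors::DataFrame(peak_id = paste0("p", 1:10),
#'     gene_id = rep(c("g1", "g2"), c(9, 1)), is_cre = TRUE)
#' callDorcs(links)
#' @export
callDorcs <- function(links, min_cres = 9) {
    min_cres <- .assertCount(min_cres, "min_cres")
    cre <- links[links$is_cre, , drop = FALSE]
    if (!nrow(cre))
        return(DataFrame(gene_id = character(0), n_cres = integer(0),
                         cre_peak_ids = I(list())))
    sets <- split(cre$peak_id, cre$gene_id)
    n <- lengths(sets)
    keep <- n >= min_cres
    sets <- sets[keep]; n <- n[keep]
    ord <- order(-n, names(sets))
    DataFrame(gene_id = names(sets)[ord], n_cres = as.integer(n[ord]),
              cre_peak_ids = I(unname(sets[ord])))
}

#' Per-cell DORC scores
#'
#' A gene's DORC score in a cell is the sum of normalized accessibility
#' over the gene's CRE peaks.
#'
#' @param multiome a \linkS4class{Multiome}.
#' @param dorcs a DORC table from [callDorcs()].
#' @param scale normalization scale.
#' @return dense matrix, DORC genes x cells.
#' @export
dorcScores <- function(multiome, dorcs, scale = 1e4) {
    stopifnot(is(multiome, "Multiome"))
    if (!nrow(dorcs)) stop("empty DORC table")
    atacN <- normalizeCounts(atacCounts(multiome), scale = scale)
    peakIds <- rownames(atacN)
    out <- matrix(0, nrow(dorcs), ncol(atacN),
                  dimnames = list(dorcs$gene_id, colnames(atacN)))
    for (i in seq_len(nrow(dorcs))) {
        ids <- dorcs$cre_peak_ids[[i]]
        miss <- setdiff(ids, peakIds)
        if (length(miss))
            stop("DORC ", dorcs$gene_id[i], " references missing peak(s): ",
                 paste(head(miss, 3), collapse = ", "))
        out[i, ] <- colSums(atacN[ids, , drop = FALSE])
    }
    out
}

#' Treatment-response correlation between DORC accessibility and expression
#'
#' For each DORC gene, computes the exposed-minus-unexposed difference in
#' mean DORC score (chromatin side) and in mean normalized expression
#' (RNA side), and returns the Pearson correlation of the two deltas
#' across DORC genes.
#'
#' @param multiome a \linkS4class{Multiome} whose cells carry both
#'   \code{"unexposed"} and \code{"oxldl"} treatment labels.
#' @param dorcs a DORC table from [callDorcs()] (>= 3 genes).
#' @param scale normalization scale.
#' @return list with \code{r}, \code{p}, \code{n_genes}, and a per-gene
#'   \code{DataFrame} of deltas.
#' @export
deltaResponseCorrelation <- function(multiome, dorcs, scale = 1e4) {
    stopifnot(is(multiome, "Multiome"))
    if (nrow(dorcs) < 3)
        stop("need at least 3 DORC genes for the delta correlation")
    trt <- cellInfo(multiome)$treatment
    if (!all(c("unexposed", "oxldl") %in% trt))
        stop("both treatment labels must be present")
    sc <- dorcScores(multiome, dorcs, scale = scale)
    rnaN <- as.matrix(normalizeCounts(rnaCounts(multiome), scale = scale))
    ex <- trt == "oxldl"
    dAcc <- rowMeans(sc[, ex, drop = FALSE]) -
        rowMeans(sc[, !ex, drop = FALSE])
    rsub <- rnaN[dorcs$gene_id, , drop = FALSE]
    dExp <- rowMeans(rsub[, ex, drop = FALSE]) -
        rowMeans(rsub[, !ex, drop = FALSE])
    r <- cor(dAcc, dExp)
    list(r = r, p = .corTestP(r, nrow(dorcs)), n_genes = nrow(dorcs),
         per_gene = DataFrame(gene_id = dorcs$gene_id,
                              delta_access = dAcc, delta_expr = dExp))
}
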