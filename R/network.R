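#' Score TF-DORC regulatory interactions
#'
#' Every TF x DORC pair is scored on two axes. Enrichment: the observed
#' motif hit count in the DORC's CRE peak set is compared with the
#' mean/sd of hit counts over \code{n_bg} matched background peak sets of
#' equal size (one background peak drawn per CRE from its matched pool);
#' \code{p_enrich} is the one-sided (over-representation) normal tail.
#' Correlation: Spearman rho between the TF gene's expression and the
#' DORC score across cells with its t-reference p-value. The signed
#' regulation score is \code{sign(rho) * min(-log10 p_enrich, -log10
#' p_corr)} -- conjunctive, so an edge needs both motif enrichment and
#' expression-accessibility coupling to score highly.
#'
#' @param dorcs DORC table from [callDorcs()].
#' @param dorc_scores DORC gene x cell matrix from [dorcScores()].
#' @param rna normalized gene x cell expression matrix.
#' @param motifs motif hits (see [computeDeviations()]).
#' @param features peak feature table from [peakFeatures()].
#' @param n_bg background sets per DORC (default 50).
#' @param pool_k matched pool size per peak (default 50).
#' @param seed RNG seed for background sampling.
#' @param tf_gene_map named character vector TF -> gene id (default: TF
#'   names are gene ids).
#' @return an EdgeTable: \code{DataFrame} with tf, dorc, n_cres,
#'   obs_hits, p_enrich, rho, p_corr, reg_score; one row per TF x DORC
#'   pair (DORCs with all-zero scores are skipped with a warning).
#' @examples
#' ## see vignette for an end-to-end example
#' @export
scoreTfDorc <- function(dorcs, dorc_scores, rna, motifs, features,
                        n_bg = 50, pool_k = 50, seed = 1,
                        tf_gene_map = NULL) {
    n_bg <- .assertCount(n_bg, "n_bg", min = 2L)
    pool_k <- .assertCount(pool_k, "pool_k")
    peakIds <- features$peak_id
    P <- .motifIndicator(motifs, peakIds)          # peak x tf
    tfs <- colnames(P)
    if (is.null(tf_gene_map)) tf_gene_map <- setNames(tfs, tfs)
    tfGene <- tf_gene_map[tfs]
    if (any(is.na(tfGene)) || !all(tfGene %in% rownames(rna)))
        stop("every TF must map to a gene present in 'rna'")

    allCre <- unique(unlist(dorcs$cre_peak_ids))
    if (!all(allCre %in% peakIds))
        stop("DORC CRE peaks missing from the peak universe")

    # drop degenerate DORCs
    zeroScore <- rowSums(abs(dorc_scores[dorcs$gene_id, , drop = FALSE])) == 0
    if (any(zeroScore)) {
        warning(sum(zeroScore), " DORC(s) with all-zero scores skipped")
        dorcs <- dorcs[!zeroScore, , drop = FALSE]
    }
    nD <- nrow(dorcs); nT <- length(tfs)
    if (!nD) stop("no scorable DORCs")

    # observed motif hits per (dorc, tf)
    D <- sparseMatrix(
        i = match(unlist(dorcs$cre_peak_ids), peakIds),
        j = rep(seq_len(nD), lengths(dorcs$cre_peak_ids)),
        x = 1, dims = c(length(peakIds), nD))
    obsHits <- as.matrix(crossprod(D, P))           # dorc x tf

    # matched background sets, one replacement peak per CRE member;
    # pools are only needed for peaks that appear in a CRE set
    set.seed(.assertCount(seed, "seed", min = 0L))
    memb <- lapply(dorcs$cre_peak_ids, function(ids) match(ids, peakIds))
    uniqCre <- sort(unique(unlist(memb)))
    pool <- .matchAllPeaks(features, k = pool_k, query = uniqCre)
    bgMean <- matrix(0, nD, nT)
    bgM2 <- matrix(0, nD, nT)
    for (b in seq_len(n_bg)) {
        drawn <- lapply(memb, function(jj)
            pool[cbind(match(jj, uniqCre),
                       sample.int(pool_k, length(jj), replace = TRUE))])
        Db <- sparseMatrix(i = unlist(drawn),
                           j = rep(seq_len(nD), lengths(drawn)),
                           x = 1, dims = c(length(peakIds), nD))
        hb <- as.matrix(crossprod(Db, P))
        bgMean <- bgMean + hb
        bgM2 <- bgM2 + hb^2
    }
    bgMean <- bgMean / n_bg
    bgSd <- sqrt(pmax(bgM2 / n_bg - bgMean^2, 0) * n_bg / (n_bg - 1))
    zEnrich <- (obsHits - bgMean) / pmax(bgSd, 1e-8)
    pEnrich <- pnorm(zEnrich, lower.tail = FALSE)
    # degenerate background spread: not enriched unless observed exceeds it
    flat <- bgSd == 0
    pEnrich[flat] <- ifelse(obsHits[flat] <= bgMean[flat], 1, 1 / (n_bg + 1))
    pEnrich <- pmin(pmax(pEnrich, 1e-300), 1)

    # Spearman between TF expression and DORC scores
    rho <- .spearmanRho(as.matrix(rna[tfGene, , drop = FALSE]),
                        dorc_scores[dorcs$gene_id, , drop = FALSE])
    pCorr <- .corTestP(rho, ncol(dorc_scores))
    pCorr <- pmin(pmax(pCorr, 1e-300), 1)

    reg <- sign(t(rho)) * pmin(-log10(pEnrich), -log10(t(pCorr)))
    reg[is.na(reg)] <- 0

    out <- DataFrame(
        tf = rep(tfs, each = nD),
        dorc = rep(dorcs$gene_id, nT),
        n_cres = rep(dorcs$n_cres, nT),
        obs_hits = as.vector(obsHits),
        p_enrich = as.vector(pEnrich),
        rho = as.vector(t(rho)),
        p_corr = as.vector(t(pCorr)),
        reg_score = as.vector(reg))
    metadata(out) <- list(n_tfs = nT, n_dorcs = nD, n_bg = n_bg,
                          seed = seed)
    out
}

#' Threshold the TF-DORC edge table into a signed regulatory network
#'
#' @param edges EdgeTable from [scoreTfDorc()].
#' @param threshold absolute regulation score cutoff (strict >; default
#'   1.5).
#' @return list with \code{edges} (source, target, score, sign) and
#'   counts: n_edges, n_tfs, n_dorcs, n_activating, n_repressive.
#' @examples
#' ed <- S4Vectors::DataFrame(tf = c("a", "b", "c"),
#'     dorc = c("g1", "g2", "g3"), reg_score = c(-2, 1.4, 1.6))
#' buildNetwork(ed, threshold = 1.5)$edges
#' @export
buildNetwork <- function(edges, threshold = 1.5) {
    keep <- !is.na(edges$reg_score) & abs(edges$reg_score) > threshold
    el <- DataFrame(source = edges$tf[keep], target = edges$dorc[keep],
                    score = edges$reg_score[keep],
                    sign = ifelse(edges$reg_score[keep] > 0,
                                  "activating", "repressive"))
    list(edges = el,
         n_edges = nrow(el),
         n_tfs = length(unique(el$source)),
         n_dorcs = length(unique(el$target)),
         n_activating = sum(el$sign == "activating"),
         n_repressive = sum(el$sign == "repressive"),
         threshold = threshold)
}
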