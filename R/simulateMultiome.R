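#' Configuration for the synthetic multiome generator
#'
#' Collects and validates all parameters of [simulateMultiome()]. Defaults
#' describe a desk-scale dataset with subpopulation-structured negative
#' binomial RNA counts, Poisson ATAC counts with gamma-distributed cell
#' depths, motif-driven peak accessibility tied to TF expression, and
#' planted peak-to-gene cis links within 500 kb.
#'
#' @param n_cells,n_genes,n_peaks,n_subpops,n_tfs dataset dimensions.
#' @param frac_linked_peaks fraction of peaks carrying a planted cis link.
#' @param links_per_gene mean number of linked peaks assigned per linked
#'   gene (links are concentrated so DORC calling is exercised).
#' @param link_effect log-scale expression shift per unit of centered,
#'   normalized peak accessibility.
#' @param treatment_frac fraction of cells labeled \code{"oxldl"}.
#' @param nb_dispersion negative binomial size parameter for RNA counts
#'   (smaller = more overdispersed).
#' @param depth_mean_rna,depth_mean_atac mean per-cell sequencing depths;
#'   per-cell depths are Gamma(shape 10) around these means.
#' @param genome_span length in bp of the single simulated chromosome
#'   \code{"chrS"}; must be >= 1e6 so 500 kb windows are nontrivial.
#' @param window_bp cis-window radius used when planting links.
#' @param motif_frac fraction of peaks hit by each TF motif.
#' @param motif_effect logit-scale accessibility shift per unit TF
#'   activity at motif-bearing peaks.
#' @param tf_expr_coupling log-scale RNA shift per unit TF activity for
#'   the TF's own gene (makes measured TF expression track activity).
#' @param subpop_sd,peak_sd standard deviations of per-subpopulation peak
#'   deviations and of global peak baselines (log scale).
#' @param treat_peak_shift accessibility shift applied, in exposed cells,
#'   to peaks linked to response genes.
#' @param treat_expr_fc direct fold change applied to response-gene means
#'   in exposed cells.
#' @param n_response_genes number of treatment-responsive genes.
#' @param n_markers_per_subpop marker genes planted per subpopulation.
#' @param gc_confounded if TRUE, peak GC tracks baseline accessibility
#'   (stress test for background matching); default independent.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"SimMultiomeConfig"}.
#' @examples
#' cfg <- simMultiomeConfig(n_cells = 100, n_genes = 50, n_peaks = 300)
#' @export
simMultiomeConfig <- function(n_cells = 2000, n_genes = 500, n_peaks = 5000,
        n_subpops = 4, n_tfs = 20, frac_linked_peaks = 0.02,
        links_per_gene = 5, link_effect = 1.0, treatment_frac = 0.5,
        nb_dispersion = 2, depth_mean_rna = 5000, depth_mean_atac = 5000,
        genome_span = 1e8, window_bp = 5e5, motif_frac = 0.05,
        motif_effect = 0.5, tf_expr_coupling = 1.0, subpop_sd = 0.3,
        peak_sd = 1.0, treat_peak_shift = 1.0, treat_expr_fc = 2,
        n_response_genes = 40, n_markers_per_subpop = 15,
        gc_confounded = FALSE, seed = 1) {
    cfg <- list(
        n_cells = .assertCount(n_cells, "n_cells"),
        n_genes = .assertCount(n_genes, "n_genes"),
        n_peaks = .assertCount(n_peaks, "n_peaks"),
        n_subpops = .assertCount(n_subpops, "n_subpops"),
        n_tfs = .assertCount(n_tfs, "n_tfs", min = 0L),
        frac_linked_peaks = .assertFraction(frac_linked_peaks,
                                            "frac_linked_peaks"),
        links_per_gene = .assertPositive(links_per_gene, "links_per_gene"),
        link_effect = as.numeric(link_effect),
        treatment_frac = .assertFraction(treatment_frac, "treatment_frac"),
        nb_dispersion = .assertPositive(nb_dispersion, "nb_dispersion"),
        depth_mean_rna = .assertPositive(depth_mean_rna, "depth_mean_rna"),
        depth_mean_atac = .assertPositive(depth_mean_atac, "depth_mean_atac"),
        genome_span = .assertPositive(genome_span, "genome_span"),
        window_bp = .assertPositive(window_bp, "window_bp"),
        motif_frac = .assertFraction(motif_frac, "motif_frac"),
        motif_effect = as.numeric(motif_effect),
        tf_expr_coupling = as.numeric(tf_expr_coupling),
        subpop_sd = .assertPositive(subpop_sd, "subpop_sd"),
        peak_sd = .assertPositive(peak_sd, "peak_sd"),
        treat_peak_shift = as.numeric(treat_peak_shift),
        treat_expr_fc = .assertPositive(treat_expr_fc, "treat_expr_fc"),
        n_response_genes = .assertCount(n_response_genes, "n_response_genes",
                                        min = 0L),
        n_markers_per_subpop = .assertCount(n_markers_per_subpop,
                                            "n_markers_per_subpop", min = 0L),
        gc_confounded = isTRUE(gc_confounded),
        seed = .assertCount(seed, "seed", min = 0L))
    if (cfg$link_effect < 0)
        stop("'link_effect' must be non-negative")
    if (cfg$genome_span < 1e6)
        stop("'genome_span' must be >= 1e6 so cis windows are nontrivial")
    class(cfg) <- "SimMultiomeConfig"
    cfg
}

#' Simulate a paired single-cell multiome dataset with planted truth
#'
#' Generates subpopulation-structured ATAC and RNA counts. Peak
#' accessibility has a per-subpopulation latent component; motif-bearing
#' peaks are shifted on the logit scale by the cell's TF activity times
#' the TF's activator/repressor sign; ATAC counts are Poisson around
#' depth-scaled softmax accessibilities. Gene means are a subpopulation
#' baseline times \code{exp(link_effect * centered normalized accessibility)}
#' summed over the gene's planted linked peaks; RNA counts are negative
#' binomial. Exposed (\code{"oxldl"}) cells get a direct fold change on a
#' designated response gene set, whose linked peaks also gain
#' accessibility, so expression and chromatin respond together.
#'
#' @param config a [simMultiomeConfig()].
#' @return list with elements \code{multiome} (a \linkS4class{Multiome})
#'   and \code{truth}: \code{true_links} (peak_id, gene_id, effect),
#'   \code{motif_hits} (tf, peak_id), \code{tf_sign} (named +1/-1),
#'   \code{tf_genes}, \code{response_genes}, \code{marker_genes}
#'   (gene, subpop), and \code{tf_program} (the planted TF -> gene
#'   regulatory pair, when links and TFs exist).
#' @examples
#' sim <- simulateMultiome(simMultiomeConfig(n_cells = 80, n_genes = 40,
#'     n_peaks = 200, seed = 7))
#' nrow(sim$truth$true_links)
#' @export
simulateMultiome <- function(config) {
    stopifnot(inherits(config, "SimMultiomeConfig"))
    cfg <- config
    set.seed(cfg$seed)
    nC <- cfg$n_cells; nG <- cfg$n_genes; nP <- cfg$n_peaks
    S <- cfg$n_subpops; nT <- min(cfg$n_tfs, nG)

    cells <- sprintf("cell%05d", seq_len(nC))
    genes <- sprintf("gene%04d", seq_len(nG))
    peakIds <- sprintf("peak%05d", seq_len(nP))

    subpop <- paste0("subpop", sample.int(S, nC, replace = TRUE))
    treatment <- ifelse(runif(nC) < cfg$treatment_frac, "oxldl", "unexposed")

    peakWidth <- 500L
    peakStart0 <- sort(sample.int(as.integer(cfg$genome_span) - peakWidth, nP))
    tssPos0 <- sort(sample.int(as.integer(cfg$genome_span), nG))
    geneStrand <- sample(c("+", "-"), nG, replace = TRUE)

    # gene roles: TFs first (by lot), then markers/response kept disjoint
    tfGenes <- if (nT > 0) sort(sample(genes, nT)) else character()
    nonTf <- setdiff(genes, tfGenes)

    # planted cis links: concentrate several peaks on each linked gene so
    # high-CRE-density genes (DORCs) exist
    nLinks <- round(cfg$frac_linked_peaks * nP)
    peakMid0 <- peakStart0 + peakWidth / 2
    linkPeak <- integer(0); linkGene <- character(0)
    if (nLinks > 0) {
        candGenes <- sample(nonTf)
        freePeaks <- rep(TRUE, nP)
        gi <- 1L
        while (length(linkPeak) < nLinks) {
            if (gi > length(candGenes))
                stop("n_peaks too small to place ", nLinks,
                     " links within ", cfg$window_bp, " bp windows")
            g <- candGenes[gi]; gi <- gi + 1L
            tss0 <- tssPos0[match(g, genes)]
            inWin <- which(freePeaks &
                           abs(peakMid0 - tss0) < cfg$window_bp)
            if (!length(inWin)) next
            k <- min(length(inWin), 1L + rpois(1L, cfg$links_per_gene - 1),
                     nLinks - length(linkPeak))
            take <- if (length(inWin) == 1L) inWin else sample(inWin, k)
            freePeaks[take] <- FALSE
            linkPeak <- c(linkPeak, take)
            linkGene <- c(linkGene, rep(g, length(take)))
        }
    }
    linkedGenes <- unique(linkGene)

    markers <- DataFrame(gene = character(0), subpop = character(0))
    if (cfg$n_markers_per_subpop > 0) {
        pool <- setdiff(nonTf, linkedGenes)
        need <- cfg$n_markers_per_subpop * S
        if (length(pool) >= need) {
            mg <- sample(pool, need)
            markers <- DataFrame(gene = mg,
                subpop = rep(paste0("subpop", seq_len(S)),
                             each = cfg$n_markers_per_subpop))
        }
    }

    # response genes act through linked peaks when links exist
    respPool <- if (length(linkedGenes)) linkedGenes else
        setdiff(nonTf, markers$gene)
    respGenes <- if (cfg$n_response_genes > 0 && length(respPool))
        sample(respPool, min(cfg$n_response_genes, length(respPool)))
        else character()
    # heterogeneous response magnitudes so genes respond to different
    # degrees (gives the delta-response correlation a real signal axis)
    respScale <- setNames(runif(length(respGenes), 0.2, 1.8), respGenes)

    # motifs and TF activity
    tfSign <- setNames(sample(c(-1, 1), nT, replace = TRUE), tfGenes)
    nHits <- max(1L, round(cfg$motif_frac * nP))
    motifHits <- DataFrame(
        tf = rep(tfGenes, each = nHits),
        peak_id = peakIds[unlist(lapply(seq_len(nT), function(i)
            sample.int(nP, nHits)))])

    # plant one TF -> gene regulatory program: the first TF's motif also
    # covers all linked peaks of the most-linked gene, so that gene's
    # chromatin tracks the TF's activity (and hence its expression)
    tfProgram <- NULL
    if (nT > 0 && length(linkPeak)) {
        gTop <- names(which.max(table(linkGene)))
        progPeaks <- peakIds[linkPeak[linkGene == gTop]]
        tfProg <- tfGenes[1L]
        add <- setdiff(progPeaks,
                       motifHits$peak_id[motifHits$tf == tfProg])
        if (length(add))
            motifHits <- rbind(motifHits,
                               DataFrame(tf = tfProg, peak_id = add))
        tfProgram <- list(tf = tfProg, gene = gTop)
    }

    tfSubpopMean <- matrix(rnorm(S * nT), S, nT)
    spIdx <- as.integer(sub("subpop", "", subpop))
    tfAct <- tfSubpopMean[spIdx, , drop = FALSE] +
        matrix(rnorm(nC * nT, sd = 0.5), nC, nT)
    colnames(tfAct) <- tfGenes

    # peak log-accessibility: global baseline + subpop deviation + motif term
    basePeak <- rnorm(nP, sd = cfg$peak_sd)
    subDev <- matrix(rnorm(S * nP, sd = cfg$subpop_sd), S, nP)
    L <- subDev[spIdx, , drop = FALSE] +
        matrix(basePeak, nC, nP, byrow = TRUE)
    if (nT > 0) {
        Msign <- sparseMatrix(
            i = match(motifHits$tf, tfGenes),
            j = match(motifHits$peak_id, peakIds),
            x = rep(tfSign[motifHits$tf] * cfg$motif_effect, 1),
            dims = c(nT, nP))
        L <- L + as.matrix(tfAct %*% Msign)
    }
    isResp <- linkGene %in% respGenes
    respPeaks <- linkPeak[isResp]
    if (length(respPeaks) && cfg$treat_peak_shift != 0) {
        shift <- cfg$treat_peak_shift * respScale[linkGene[isResp]]
        L[treatment == "oxldl", respPeaks] <-
            sweep(L[treatment == "oxldl", respPeaks, drop = FALSE], 2L,
                  shift, "+")
    }

    gc <- if (cfg$gc_confounded)
        0.3 + 0.4 * (rank(basePeak) - 0.5) / nP else runif(nP, 0.3, 0.7)

    prob <- exp(L - apply(L, 1L, max))
    prob <- prob / rowSums(prob)
    depthAtac <- rgamma(nC, shape = 10, rate = 10 / cfg$depth_mean_atac)
    Xatac <- matrix(rpois(nC * nP, depthAtac * prob), nC, nP)

    # normalized, centered accessibility feeds linked-gene means
    obsDepth <- pmax(rowSums(Xatac), 1)
    geneLogBase <- rnorm(nG, sd = 0.5)
    logMu <- matrix(geneLogBase, nC, nG, byrow = TRUE)
    if (nrow(markers)) {
        mIdx <- cbind(match(markers$gene, genes))
        for (i in seq_len(nrow(markers))) {
            sel <- subpop == markers$subpop[i]
            logMu[sel, mIdx[i]] <- logMu[sel, mIdx[i]] + 2 * log(2)
        }
    }
    if (nT > 0 && cfg$tf_expr_coupling != 0)
        logMu[, match(tfGenes, genes)] <-
            logMu[, match(tfGenes, genes)] + cfg$tf_expr_coupling * tfAct
    if (length(linkPeak) && cfg$link_effect != 0) {
        v <- log1p(Xatac[, linkPeak, drop = FALSE] / obsDepth * 1e4)
        v <- scale(v, center = TRUE, scale = FALSE)
        gIdx <- match(linkGene, genes)
        for (j in seq_along(linkPeak))
            logMu[, gIdx[j]] <- logMu[, gIdx[j]] + cfg$link_effect * v[, j]
    }
    if (length(respGenes))
        logMu[treatment == "oxldl", match(respGenes, genes)] <-
            sweep(logMu[treatment == "oxldl", match(respGenes, genes),
                        drop = FALSE], 2L,
                  log(cfg$treat_expr_fc) * respScale[respGenes], "+")

    pG <- exp(logMu - apply(logMu, 1L, max))
    pG <- pG / rowSums(pG)
    depthRna <- rgamma(nC, shape = 10, rate = 10 / cfg$depth_mean_rna)
    Xrna <- matrix(rnbinom(nC * nG, mu = depthRna * pG,
                           size = cfg$nb_dispersion), nC, nG)

    peaks <- GRanges("chrS", IRanges(start = peakStart0 + 1L,
                                     width = peakWidth))
    names(peaks) <- peakIds
    mcols(peaks)$gc <- gc
    tss <- GRanges("chrS", IRanges(start = tssPos0 + 1L, width = 1L),
                   strand = geneStrand)
    names(tss) <- genes

    rna <- as(as(as(t(Xrna), "dMatrix"), "generalMatrix"), "CsparseMatrix")
    dimnames(rna) <- list(genes, cells)
    atac <- as(as(as(t(Xatac), "dMatrix"), "generalMatrix"), "CsparseMatrix")
    dimnames(atac) <- list(peakIds, cells)

    mm <- Multiome(rna = rna, atac = atac, peaks = peaks, tss = tss,
                   cellData = DataFrame(subpop = subpop,
                                        treatment = treatment,
                                        row.names = cells))
    truth <- list(
        true_links = DataFrame(peak_id = peakIds[linkPeak],
                               gene_id = linkGene,
                               effect = rep(cfg$link_effect,
                                            length(linkPeak))),
        motif_hits = motifHits,
        tf_sign = tfSign,
        tf_genes = tfGenes,
        response_genes = respGenes,
        marker_genes = markers,
        tf_program = tfProgram,
        seed = cfg$seed)
    list(multiome = mm, truth = truth)
}
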