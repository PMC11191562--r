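.pipelineDefaults <- function() list(
    outdir = NULL,
    seed = 1,
    sim = list(n_cells = 800, n_genes = 250, n_peaks = 2500,
               n_subpops = 3, n_tfs = 10, frac_linked_peaks = 0.048,
               links_per_gene = 12, link_effect = 1.0,
               treatment_frac = 0.5, genome_span = 3e7),
    panel = list(n_ind = 120, n_blocks = 40, block_size = 25,
                 decay = 0.9, spacing = 1000),
    snps = list(frac_in_peaks = 0.5, enrichment = 3),
    gwas = list(n_gwas = 5000, h2 = 0.3, prop_h2_cre = 0.5),
    link = list(window_bp = 5e5, n_bg = 100, fdr_cut = 0.05),
    dorc = list(min_cres = 9),
    chromvar = list(n_bg = 25, pool_k = 50),
    figr = list(n_bg = 25, pool_k = 50, threshold = 1.5),
    overlap = list(n_leads = 15, r2_cut = 0.8, n_perm = 500, pool_k = 50),
    h2 = list(window_bp = 1e6, n_blocks = 100, mode = "weighted"))

#' Assemble and validate a pipeline configuration
#'
#' Merges user settings over the package defaults. Unknown keys (at the
#' top level or within a stage block) are rejected, so typos fail fast.
#'
#' @param outdir output directory for all pipeline artifacts.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param ... stage blocks (\code{sim}, \code{panel}, \code{snps},
#'   \code{gwas}, \code{link}, \code{dorc}, \code{chromvar},
#'   \code{figr}, \code{overlap}, \code{h2}) as named lists overriding
#'   individual defaults.
#' @return a validated config list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(tempfile(), seed = 7,
#'     sim = list(n_cells = 200, n_genes = 60, n_peaks = 400))
#' @export
pipelineConfig <- function(outdir, seed = 1, ...) {
    defs <- .pipelineDefaults()
    user <- list(...)
    bad <- setdiff(names(user), names(defs))
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (blk in names(user)) {
        if (!is.list(user[[blk]]))
            stop("config block '", blk, "' must be a list")
        badk <- setdiff(names(user[[blk]]), names(defs[[blk]]))
        if (length(badk))
            stop("unknown key(s) in '", blk, "': ",
                 paste(badk, collapse = ", "))
        defs[[blk]][names(user[[blk]])] <- user[[blk]]
    }
    defs$outdir <- outdir
    defs$seed <- .assertCount(seed, "seed", min = 0L)
    class(defs) <- "PipelineConfig"
    defs
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipelineConfig()].
#' @param outdir optional override of the configured output directory.
#' @return a validated \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path, outdir = NULL) {
    y <- yaml::read_yaml(path)
    if (is.null(outdir)) outdir <- y$outdir
    if (is.null(outdir))
        stop("config must provide 'outdir'")
    seed <- if (is.null(y$seed)) 1 else y$seed
    y$outdir <- NULL; y$seed <- NULL; y$package_version <- NULL
    do.call(pipelineConfig, c(list(outdir = outdir, seed = seed), y))
}

.stageLog <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

.pipeSimulate <- function(cfg) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    simcfg <- do.call(simMultiomeConfig, c(cfg$sim, list(seed = cfg$seed)))
    sim <- simulateMultiome(simcfg)
    .stageLog("simulate", "seed=", cfg$seed, " cells=", nCells(sim$multiome),
              " planted links=", nrow(sim$truth$true_links))
    writeMultiome(sim$multiome, file.path(cfg$outdir, "multiome"))
    .writeTsv(as.data.frame(sim$truth$true_links),
              file.path(cfg$outdir, "true_links.tsv"),
              meta = sprintf("seed=%d", cfg$seed))
    .writeTsv(as.data.frame(sim$truth$motif_hits),
              file.path(cfg$outdir, "motif_hits.tsv"),
              meta = sprintf("seed=%d", cfg$seed))
    .writeTsv(data.frame(tf = names(sim$truth$tf_sign),
                         sign = sim$truth$tf_sign),
              file.path(cfg$outdir, "tf_sign.tsv"),
              meta = sprintf("seed=%d", cfg$seed))

    panel <- do.call(simulateLDPanel,
                     c(cfg$panel, list(seed = cfg$seed + 11L)))
    write.table(panel@haplotypes,
                file.path(cfg$outdir, "panel_haplotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    .writeTsv(as.data.frame(snpInfo(panel)),
              file.path(cfg$outdir, "panel_snps.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 11L))

    linkedPeaks <- unique(sim$truth$true_links$peak_id)
    snpPos <- placeSnps(panel, peakRanges(sim$multiome),
                        frac_in_peaks = cfg$snps$frac_in_peaks,
                        cre_peaks = if (length(linkedPeaks)) linkedPeaks
                                    else NULL,
                        enrichment = cfg$snps$enrichment,
                        seed = cfg$seed + 12L)
    .writeTsv(as.data.frame(snpPos),
              file.path(cfg$outdir, "snp_positions.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 12L))

    # planted per-SNP heritability: extra weight on SNPs in linked peaks
    M <- ncol(panel@haplotypes)
    inLinked <- rep(0, M)
    if (length(linkedPeaks)) {
        pk <- peakRanges(sim$multiome)[linkedPeaks]
        ov <- findOverlaps(GRanges(snpPos$chrom,
                                   IRanges(snpPos$pos, width = 1L)), pk)
        inLinked[unique(S4Vectors::queryHits(ov))] <- 1
    }
    h2 <- cfg$gwas$h2
    nIn <- sum(inLinked)
    if (nIn > 0 && nIn < M) {
        tauBase <- h2 * (1 - cfg$gwas$prop_h2_cre) / (M - nIn)
        tauCre <- h2 * cfg$gwas$prop_h2_cre / nIn - tauBase
        ann <- cbind(base = rep(1, M), cre = inLinked)
        tau <- c(tauBase, tauCre)
    } else {
        ann <- cbind(base = rep(1, M))
        tau <- h2 / M
    }
    ss <- simulateSumstats(panel, ann, tau, n_gwas = cfg$gwas$n_gwas,
                           seed = cfg$seed + 13L)
    writeSumstats(ss, file.path(cfg$outdir, "sumstats.tsv"))
    .stageLog("simulate", "panel M=", M, " SNPs in linked peaks=", nIn)
    invisible(NULL)
}

.pipeLink <- function(cfg) {
    mm <- readMultiome(file.path(cfg$outdir, "multiome"))
    links <- linkPeaksToGenes(mm, window_bp = cfg$link$window_bp,
                              n_bg = cfg$link$n_bg,
                              fdr_cut = cfg$link$fdr_cut)
    .stageLog("link", "tested pairs=", nrow(links),
              " CREs=", sum(links$is_cre))
    writeLinkTable(links, file.path(cfg$outdir, "links.tsv"),
                   seed = cfg$seed)
    invisible(NULL)
}

.readLinks <- function(cfg) {
    d <- .readTsv(file.path(cfg$outdir, "links.tsv"))
    d$is_cre <- as.logical(d$is_cre)
    as(d, "DataFrame")
}

.pipeDorc <- function(cfg) {
    mm <- readMultiome(file.path(cfg$outdir, "multiome"))
    links <- .readLinks(cfg)
    dorcs <- callDorcs(links, min_cres = cfg$dorc$min_cres)
    .stageLog("dorc", "DORC genes=", nrow(dorcs))
    if (!nrow(dorcs))
        stop("dorc stage: no genes reach ", cfg$dorc$min_cres, " CREs")
    .writeTsv(data.frame(gene_id = dorcs$gene_id, n_cres = dorcs$n_cres,
                         cre_peak_ids = vapply(dorcs$cre_peak_ids,
                                               paste, "", collapse = ",")),
              file.path(cfg$outdir, "dorcs.tsv"),
              meta = sprintf("seed=%d", cfg$seed))
    sc <- dorcScores(mm, dorcs)
    write.table(round(sc, 6), file.path(cfg$outdir, "dorc_scores.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    if (nrow(dorcs) >= 3) {
        dc <- deltaResponseCorrelation(mm, dorcs)
        .writeTsv(data.frame(r = dc$r, p = dc$p, n_genes = dc$n_genes),
                  file.path(cfg$outdir, "delta_cor.tsv"),
                  meta = sprintf("seed=%d", cfg$seed))
        .stageLog("dorc", "delta-response correlation R=",
                  sprintf("%.3f", dc$r))
    }
    invisible(NULL)
}

.pipeChromvar <- function(cfg) {
    mm <- readMultiome(file.path(cfg$outdir, "multiome"))
    hits <- .readTsv(file.path(cfg$outdir, "motif_hits.tsv"))
    dev <- computeDeviations(mm, hits, n_bg = cfg$chromvar$n_bg,
                             pool_k = cfg$chromvar$pool_k,
                             seed = cfg$seed + 21L)
    write.table(round(deviationScores(dev, "z"), 6),
                file.path(cfg$outdir, "dev_z.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    rnaN <- normalizeCounts(rnaCounts(mm))
    tab <- deviationExpressionCorrelation(dev, rnaN)
    .writeTsv(as.data.frame(tab), file.path(cfg$outdir, "dev_expr_cor.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 21L))
    .stageLog("chromvar", "TFs=", nrow(tab), " significant=",
              sum(tab$class != "ns"))
    invisible(NULL)
}

.pipeFigr <- function(cfg) {
    mm <- readMultiome(file.path(cfg$outdir, "multiome"))
    links <- .readLinks(cfg)
    dorcs <- callDorcs(links, min_cres = cfg$dorc$min_cres)
    if (!nrow(dorcs)) stop("figr stage: no DORCs available")
    sc <- dorcScores(mm, dorcs)
    hits <- .readTsv(file.path(cfg$outdir, "motif_hits.tsv"))
    feats <- peakFeatures(mm)
    rnaN <- normalizeCounts(rnaCounts(mm))
    edges <- scoreTfDorc(dorcs, sc, rnaN, hits, feats,
                         n_bg = cfg$figr$n_bg, pool_k = cfg$figr$pool_k,
                         seed = cfg$seed + 31L)
    .writeTsv(as.data.frame(edges), file.path(cfg$outdir, "edges.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 31L))
    net <- buildNetwork(edges, threshold = cfg$figr$threshold)
    .writeTsv(as.data.frame(net$edges), file.path(cfg$outdir, "network.tsv"),
              meta = sprintf("seed=%d threshold=%s", cfg$seed + 31L,
                             cfg$figr$threshold))
    .stageLog("figr", "scored pairs=", nrow(edges), " strong edges=",
              net$n_edges)
    invisible(NULL)
}

.pipeOverlap <- function(cfg) {
    mm <- readMultiome(file.path(cfg$outdir, "multiome"))
    links <- .readLinks(cfg)
    snpPos <- .readTsv(file.path(cfg$outdir, "snp_positions.tsv"))
    haps <- as.matrix(read.delim(file.path(cfg$outdir,
                                           "panel_haplotypes.tsv")))
    st <- .readTsv(file.path(cfg$outdir, "panel_snps.tsv"))
    panel <- new("LDPanel", haplotypes = haps,
                 snpTable = as(st, "DataFrame"),
                 blockBounds = as.integer(which(!duplicated(st$block))),
                 decay = cfg$panel$decay)
    cre <- links[links$is_cre, , drop = FALSE]
    if (!nrow(cre)) stop("gwas-overlap stage: no CREs in the link table")
    creGR <- GRanges(cre$chrom, IRanges(cre$peak_start + 1L, cre$peak_end))
    inCre <- unique(snpPos$snp_id[S4Vectors::queryHits(findOverlaps(
        GRanges(snpPos$chrom, IRanges(snpPos$pos, width = 1L)), creGR))])
    set.seed(cfg$seed + 41L)
    leads <- if (length(inCre))
        sample(inCre, min(cfg$overlap$n_leads, length(inCre)))
        else sample(snpPos$snp_id, cfg$overlap$n_leads)
    ldp <- panelLdPairs(panel, r2_min = cfg$overlap$r2_cut)
    snps <- expandLD(leads, ldp, r2_cut = cfg$overlap$r2_cut,
                     snp_info = snpPos)
    .writeTsv(as.data.frame(snps), file.path(cfg$outdir, "snp_table.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 41L))
    mp <- mapSnpsToGenes(snps, links, tssRanges(mm))
    .writeTsv(as.data.frame(mp$pairs), file.path(cfg$outdir, "snp_gene_pairs.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 41L))
    .writeTsv(data.frame(metric = names(mp$summary),
                         value = unlist(mp$summary)),
              file.path(cfg$outdir, "snp_gene_summary.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 41L))
    pe <- permutationEnrichment(snps, unique(cre$peak_id),
                                peakRanges(mm), peakFeatures(mm),
                                n_perm = cfg$overlap$n_perm,
                                pool_k = cfg$overlap$pool_k,
                                seed = cfg$seed + 42L)
    .writeTsv(data.frame(observed = pe$observed, p_emp = pe$p_emp,
                         n_perm = cfg$overlap$n_perm),
              file.path(cfg$outdir, "perm_enrichment.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 42L))
    .writeTsv(data.frame(null_count = pe$null),
              file.path(cfg$outdir, "perm_null.tsv"),
              meta = sprintf("seed=%d", cfg$seed + 42L))
    .stageLog("gwas-overlap", "LD-expanded SNPs=", nrow(snps),
              " in CREs=", mp$summary$n_snps_in_cres,
              " permutation p=", sprintf("%.4g", pe$p_emp))
    invisible(NULL)
}

.pipeH2 <- function(cfg) {
    mm <- readMultiome(file.path(cfg$outdir, "multiome"))
    links <- .readLinks(cfg)
    snpPos <- .readTsv(file.path(cfg$outdir, "snp_positions.tsv"))
    haps <- as.matrix(read.delim(file.path(cfg$outdir,
                                           "panel_haplotypes.tsv")))
    st <- .readTsv(file.path(cfg$outdir, "panel_snps.tsv"))
    panel <- new("LDPanel", haplotypes = haps,
                 snpTable = as(st, "DataFrame"),
                 blockBounds = as.integer(which(!duplicated(st$block))),
                 decay = cfg$panel$decay)
    ss <- readSumstats(file.path(cfg$outdir, "sumstats.tsv"))
    rnaN <- normalizeCounts(rnaCounts(mm))
    cd <- cellInfo(mm)

    progs <- list()
    for (sp in sort(unique(cd$subpop))) {
        lab <- ifelse(cd$subpop == sp, sp, "rest")
        de <- differentialStats(rnaN, lab, c(sp, "rest"))
        w <- tryCatch(buildGeneProgram(de, mode = cfg$h2$mode),
                      error = function(e) NULL)
        if (!is.null(w))
            progs[[sp]] <- programToAnnotation(w, links, snpPos)
    }
    deOx <- differentialStats(rnaN, cd$treatment, c("oxldl", "unexposed"))
    wOx <- tryCatch(buildGeneProgram(deOx, mode = cfg$h2$mode),
                    error = function(e) NULL)
    if (!is.null(wOx))
        progs[["pseudobulk_oxldl"]] <- programToAnnotation(wOx, links,
                                                           snpPos)
    # background: SNP inside any peak
    ovAll <- findOverlaps(GRanges(snpPos$chrom,
                                  IRanges(snpPos$pos, width = 1L)),
                          peakRanges(mm))
    bg <- numeric(nrow(snpPos))
    bg[unique(S4Vectors::queryHits(ovAll))] <- 1

    progs <- progs[vapply(progs, function(a) sd(a) > 0, TRUE)]
    if (!length(progs))
        stop("partition-h2 stage: no program annotation with variation")
    res <- conditionalTauStar(ss, panel, progs, background = bg,
                              window_bp = cfg$h2$window_bp,
                              n_blocks = cfg$h2$n_blocks)
    tab <- as.data.frame(sldscCoefs(res$fit))
    .writeTsv(tab, file.path(cfg$outdir, "sldsc.tsv"),
              meta = sprintf("seed=%d", cfg$seed))
    write_json(list(h2 = h2Estimate(res$fit),
                    intercept = sldscIntercept(res$fit),
                    tau_star = setNames(as.list(res$tau_star$tau_star),
                                        res$tau_star$annotation)),
               file.path(cfg$outdir, "sldsc.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .stageLog("partition-h2", "programs=", length(progs),
              " h2=", sprintf("%.3f", h2Estimate(res$fit)))
    invisible(NULL)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in order, each persisting its outputs
#' under \code{config$outdir} and re-reading its inputs from there, so
#' any stage can be rerun from the persisted state. The resolved
#' configuration is written beside the outputs (with \code{outdir}
#' recorded as \code{"."} so reruns in different directories are
#' byte-identical). A stage failure aborts with the stage name.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()].
#' @param stages character vector of stages, subset of
#'   \code{c("simulate", "link", "dorc", "chromvar", "figr",
#'   "gwas-overlap", "partition-h2")}, or \code{"all"}.
#' @return invisibly, the output directory.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(tempfile(), seed = 1,
#'     sim = list(n_cells = 300, n_genes = 100, n_peaks = 800,
#'                genome_span = 1e7))
#' runPipeline(cfg, stages = c("simulate", "link"))
#' }
#' @export
runPipeline <- function(config, stages = "all") {
    stopifnot(inherits(config, "PipelineConfig"))
    all_stages <- c("simulate", "link", "dorc", "chromvar", "figr",
                    "gwas-overlap", "partition-h2")
    if (identical(stages, "all")) stages <- all_stages
    bad <- setdiff(stages, all_stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    resolved <- unclass(config)
    resolved$outdir <- "."
    resolved$package_version <- as.character(packageVersion("macroCRE"))
    yaml::write_yaml(resolved, file.path(config$outdir, "config.yaml"))
    runners <- list("simulate" = .pipeSimulate, "link" = .pipeLink,
                    "dorc" = .pipeDorc, "chromvar" = .pipeChromvar,
                    "figr" = .pipeFigr, "gwas-overlap" = .pipeOverlap,
                    "partition-h2" = .pipeH2)
    for (sg in stages) {
        ok <- tryCatch({ runners[[sg]](config); TRUE },
                       error = function(e) {
                           stop("stage '", sg, "' failed: ",
                                conditionMessage(e), call. = FALSE)
                       })
    }
    invisible(config$outdir)
}
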