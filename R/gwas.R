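#' Expand lead GWAS SNPs by linkage disequilibrium
#'
#' Returns the lead SNPs plus every SNP whose r-squared with any lead
#' exceeds \code{r2_cut} (strict inequality). Each non-lead SNP is tagged
#' with the lead to which it has the highest r-squared. LD is not
#' chained: a SNP enters only through its direct r-squared with a lead.
#'
#' @param leads character vector of lead SNP ids.
#' @param ld_pairs table (DataFrame/data.frame) with columns snp_a,
#'   snp_b, r2; symmetrized internally.
#' @param r2_cut r-squared threshold (default 0.8, strict >).
#' @param snp_info optional table with snp_id, chrom, pos to attach
#'   coordinates.
#' @return SnpTable: \code{DataFrame} with snp_id, is_lead, source_lead,
#'   r2_with_lead (1 for leads), plus chrom/pos when \code{snp_info} is
#'   given. Leads absent from the LD table are retained alone with a
#'   warning.
#' @examples
#' ld <- data.frame(snp_a = c("a", "b", "a"), snp_b = c("b", "c", "c"),
#'     r2 = c(0.9, 0.9, 0.3))
#' expandLD("a", ld)$snp_id
#' @export
expandLD <- function(leads, ld_pairs, r2_cut = 0.8, snp_info = NULL) {
    leads <- unique(as.character(leads))
    lp <- as.data.frame(ld_pairs)
    if (!all(c("snp_a", "snp_b", "r2") %in% colnames(lp)))
        stop("ld_pairs needs columns snp_a, snp_b, r2")
    if (any(lp$r2 < 0 | lp$r2 > 1)) stop("r2 must lie in [0,1]")
    sym <- rbind(lp[, c("snp_a", "snp_b", "r2")],
                 data.frame(snp_a = lp$snp_b, snp_b = lp$snp_a,
                            r2 = lp$r2))
    known <- leads %in% c(sym$snp_a)
    if (!all(known))
        warning(sum(!known), " lead(s) absent from the LD table retained ",
                "alone: ", paste(head(leads[!known], 3), collapse = ", "))
    part <- sym[sym$snp_a %in% leads & sym$r2 > r2_cut &
                !(sym$snp_b %in% leads), , drop = FALSE]
    out <- DataFrame(snp_id = leads, is_lead = TRUE, source_lead = leads,
                     r2_with_lead = 1)
    if (nrow(part)) {
        # keep the max-r2 lead per partner
        ord <- order(part$snp_b, -part$r2)
        part <- part[ord, , drop = FALSE]
        part <- part[!duplicated(part$snp_b), , drop = FALSE]
        out <- rbind(out, DataFrame(snp_id = part$snp_b, is_lead = FALSE,
                                    source_lead = part$snp_a,
                                    r2_with_lead = part$r2))
    }
    if (!is.null(snp_info)) {
        si <- as.data.frame(snp_info)
        m <- match(out$snp_id, si$snp_id)
        out$chrom <- si$chrom[m]
        out$pos <- si$pos[m]
    }
    out
}

#' Map CRE-overlapping SNPs to their cis-regulated genes
#'
#' Tests SNP-in-CRE containment under the 0-based half-open convention
#' (input positions are 1-based, VCF-style) and expands each contained
#' SNP over all genes linked to the containing CRE. The summary reports
#' the counts and distance/nearest-gene/eQTL concordance fractions.
#'
#' @param snps table with snp_id, chrom, pos (1-based).
#' @param links LinkTable from [linkPeaksToGenes()] (CRE rows are used).
#' @param tss named width-1 \code{GRanges} of gene TSS positions.
#' @param eqtl optional table with columns snp_id, gene_id of known eQTL
#'   pairs; enables the eQTL concordance columns.
#' @return list with \code{pairs} (snp_id, peak_id, gene_id, distance_bp,
#'   is_nearest_gene, and eqtl_concordant when eqtl given) and
#'   \code{summary} (n_snps_tested, n_snps_in_cres, n_genes, n_pairs,
#'   median_distance_bp, frac_pairs_gt10kb, frac_pairs_nearest_gene,
#'   and pct_cre_snps_eqtl / frac_pairs_eqtl_concordant when eqtl given).
#' @export
mapSnpsToGenes <- function(snps, links, tss, eqtl = NULL) {
    sn <- as.data.frame(snps)
    if (!all(c("snp_id", "chrom", "pos") %in% colnames(sn)))
        stop("snps needs columns snp_id, chrom, pos")
    if (any(is.na(sn$pos)) || any(sn$pos < 1))
        stop("SNP positions must be 1-based positive integers")
    cre <- links[links$is_cre, , drop = FALSE]
    if (any(cre$peak_end <= cre$peak_start))
        stop("malformed CRE intervals (end <= start)")
    empty <- DataFrame(snp_id = character(0), peak_id = character(0),
                       gene_id = character(0), distance_bp = numeric(0),
                       is_nearest_gene = logical(0))
    if (!nrow(cre) || !nrow(sn)) {
        return(list(pairs = empty,
                    summary = list(n_snps_tested = nrow(sn),
                                   n_snps_in_cres = 0L, n_genes = 0L,
                                   n_pairs = 0L)))
    }
    # 1-based GRanges [start0+1, end0] == 0-based half-open [start0, end0)
    snpGR <- GRanges(sn$chrom, IRanges(sn$pos, width = 1L))
    creGR <- GRanges(cre$chrom,
                     IRanges(cre$peak_start + 1L, cre$peak_end))
    ov <- findOverlaps(snpGR, creGR)
    si <- S4Vectors::queryHits(ov)
    ci <- S4Vectors::subjectHits(ov)
    if (!length(si)) {
        return(list(pairs = empty,
                    summary = list(n_snps_tested = nrow(sn),
                                   n_snps_in_cres = 0L, n_genes = 0L,
                                   n_pairs = 0L)))
    }
    tss0 <- setNames(start(tss) - 1, names(tss))
    tssChr <- setNames(as.character(seqnames(tss)), names(tss))
    pos0 <- sn$pos[si] - 1
    gene <- cre$gene_id[ci]
    dist <- abs(pos0 - tss0[gene])

    # nearest gene per SNP (same chromosome)
    nearest <- vapply(seq_len(nrow(sn)), function(i) {
        onChr <- names(tss0)[tssChr == sn$chrom[i]]
        if (!length(onChr)) return(NA_character_)
        d <- abs((sn$pos[i] - 1) - tss0[onChr])
        onChr[which.min(d)]
    }, "")

    pairs <- DataFrame(snp_id = sn$snp_id[si],
                       peak_id = cre$peak_id[ci],
                       gene_id = gene,
                       distance_bp = unname(dist),
                       is_nearest_gene = gene == nearest[si])
    # drop duplicate (snp, peak, gene) rows for idempotence
    key <- paste(pairs$snp_id, pairs$peak_id, pairs$gene_id)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    pairs <- pairs[order(pairs$snp_id, pairs$peak_id, pairs$gene_id), ,
                   drop = FALSE]

    summ <- list(n_snps_tested = nrow(sn),
                 n_snps_in_cres = length(unique(pairs$snp_id)),
                 n_genes = length(unique(pairs$gene_id)),
                 n_pairs = nrow(pairs),
                 median_distance_bp = median(pairs$distance_bp),
                 frac_pairs_gt10kb = mean(pairs$distance_bp > 1e4),
                 frac_pairs_nearest_gene = mean(pairs$is_nearest_gene))
    if (!is.null(eqtl)) {
        eq <- as.data.frame(eqtl)
        if (!all(c("snp_id", "gene_id") %in% colnames(eq)))
            stop("eqtl needs columns snp_id, gene_id")
        pairs$eqtl_concordant <- paste(pairs$snp_id, pairs$gene_id) %in%
            paste(eq$snp_id, eq$gene_id)
        summ$pct_cre_snps_eqtl <-
            100 * mean(unique(pairs$snp_id) %in% eq$snp_id)
        summ$frac_pairs_eqtl_concordant <- mean(pairs$eqtl_concordant)
    }
    list(pairs = pairs, summary = summ)
}

#' Matched-background permutation test for SNP-in-CRE enrichment
#'
#' Counts the SNPs falling inside any CRE peak, then builds a null by
#' replacing, in each of \code{n_perm} permutations, every CRE peak with
#' one peak drawn uniformly from its \code{pool_k} GC/accessibility-
#' matched non-CRE peaks and recounting. The empirical p-value uses the
#' add-one estimator \code{(1 + #\{null >= observed\}) / (1 + n_perm)},
#' so it can never be 0 and is bounded below by \code{1/(n_perm+1)}.
#'
#' @param snps table with snp_id, chrom, pos (1-based).
#' @param cre_peaks character vector of CRE peak ids.
#' @param peaks named \code{GRanges} of all peaks (the peak universe).
#' @param features peak feature table from [peakFeatures()] covering the
#'   same peaks.
#' @param n_perm number of permutations (default 1000).
#' @param pool_k matched pool size per CRE peak (default 50); requires at
#'   least \code{pool_k} non-CRE peaks.
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{null} (integer vector length
#'   n_perm), and \code{p_emp}.
#' @export
permutationEnrichment <- function(snps, cre_peaks, peaks, features,
                                  n_perm = 1000, pool_k = 50, seed = 1) {
    n_perm <- .assertCount(n_perm, "n_perm")
    pool_k <- .assertCount(pool_k, "pool_k")
    sn <- as.data.frame(snps)
    peakIds <- names(peaks)
    if (!all(cre_peaks %in% peakIds))
        stop("cre_peaks must be a subset of the peak universe")
    creIdx <- match(cre_peaks, peakIds)
    nonCre <- setdiff(seq_along(peakIds), creIdx)
    if (length(nonCre) < pool_k + 1L)
        stop("fewer non-CRE peaks than needed for matching (need > ",
             pool_k, ")")
    # SNP ids per peak, 0-based half-open containment
    snpGR <- GRanges(sn$chrom, IRanges(sn$pos, width = 1L))
    ov <- findOverlaps(snpGR, peaks)
    snpsByPeak <- split(S4Vectors::queryHits(ov),
                        factor(S4Vectors::subjectHits(ov),
                               levels = seq_along(peakIds)))
    observed <- length(unique(unlist(snpsByPeak[creIdx], use.names = FALSE)))

    pool <- .matchAllPeaks(features, k = pool_k, query = creIdx,
                           candidates = nonCre)
    set.seed(.assertCount(seed, "seed", min = 0L))
    nullCounts <- integer(n_perm)
    nCre <- length(creIdx)
    for (b in seq_len(n_perm)) {
        drawn <- pool[cbind(seq_len(nCre),
                            sample.int(pool_k, nCre, replace = TRUE))]
        nullCounts[b] <- length(unique(unlist(snpsByPeak[drawn],
                                              use.names = FALSE)))
    }
    p <- (1 + sum(nullCounts >= observed)) / (1 + n_perm)
    list(observed = observed, null = nullCounts, p_emp = p)
}

#' Place synthetic SNPs on the multiome genome
#'
#' Assigns each panel SNP a position in the multiome coordinate system:
#' with probability \code{frac_in_peaks} the SNP lands uniformly inside a
#' peak (peaks chosen with probability proportional to width, multiplied
#' by \code{enrichment} for peaks in \code{cre_peaks}), otherwise
#' uniformly on the chromosome. This is the explicit SNP-position table
#' coupling the GWAS panel to the multiome genome.
#'
#' @param panel an \linkS4class{LDPanel} (or a character vector of SNP
#'   ids).
#' @param peaks named \code{GRanges} of peaks.
#' @param frac_in_peaks fraction of SNPs placed inside peaks.
#' @param cre_peaks optional peak ids whose selection probability is
#'   multiplied by \code{enrichment}.
#' @param enrichment selection multiplier for \code{cre_peaks} (default
#'   1 = no planted enrichment).
#' @param genome_span chromosome length for off-peak placement (default:
#'   max peak end + 10 kb).
#' @param seed RNG seed.
#' @return \code{DataFrame} with snp_id, chrom, pos (1-based).
#' @export
placeSnps <- function(panel, peaks, frac_in_peaks = 0.3, cre_peaks = NULL,
                      enrichment = 1, genome_span = NULL, seed = 1) {
    ids <- if (is(panel, "LDPanel")) snpInfo(panel)$snp_id
           else as.character(panel)
    .assertFraction(frac_in_peaks, "frac_in_peaks")
    .assertPositive(enrichment, "enrichment")
    set.seed(.assertCount(seed, "seed", min = 0L))
    n <- length(ids)
    if (is.null(genome_span)) genome_span <- max(end(peaks)) + 1e4
    chrom <- as.character(seqnames(peaks))[1L]
    w <- width(peaks)
    prob <- as.numeric(w)
    if (!is.null(cre_peaks) && enrichment != 1) {
        stopifnot(all(cre_peaks %in% names(peaks)))
        prob[names(peaks) %in% cre_peaks] <-
            prob[names(peaks) %in% cre_peaks] * enrichment
    }
    inPeak <- runif(n) < frac_in_peaks
    pos <- integer(n)
    if (any(inPeak)) {
        pk <- sample.int(length(peaks), sum(inPeak), replace = TRUE,
                         prob = prob)
        pos[inPeak] <- start(peaks)[pk] +
            floor(runif(sum(inPeak)) * w[pk])
    }
    if (any(!inPeak))
        pos[!inPeak] <- 1L + floor(runif(sum(!inPeak)) * genome_span)
    DataFrame(snp_id = ids, chrom = chrom, pos = as.integer(pos))
}
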