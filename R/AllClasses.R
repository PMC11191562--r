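#' @include AllGenerics.R
NULL

#' Paired single-cell multiome container
#'
#' Holds paired RNA and ATAC count matrices (features x cells, sparse),
#' peak intervals with GC content, gene TSS positions, and per-cell
#' metadata (subpopulation and treatment labels). Peak and TSS coordinates
#' are stored as \linkS4class{GRanges} (1-based closed, the GRanges
#' convention); exporters convert to 0-based half-open BED.
#'
#' @slot rna sparse gene x cell integer count matrix.
#' @slot atac sparse peak x cell integer count matrix.
#' @slot peaks \code{GRanges} of peak intervals, names are peak ids, with
#'   metadata column \code{gc} (GC fraction in [0,1]).
#' @slot tss width-1 \code{GRanges} at each gene's strand-aware TSS,
#'   names are gene ids.
#' @slot cellData \code{DataFrame} with at least columns \code{subpop}
#'   and \code{treatment} (\code{"unexposed"} or \code{"oxldl"}).
#'
#' @seealso [Multiome()] the constructor, [simulateMultiome()]
#' @export
setClass("Multiome",
    slots = c(rna = "dgCMatrix", atac = "dgCMatrix", peaks = "GRanges",
              tss = "GRanges", cellData = "DFrame"))

setValidity("Multiome", function(object) {
    msg <- character()
    if (ncol(object@rna) != ncol(object@atac))
        msg <- c(msg, "rna and atac must have the same number of cells")
    if (nrow(object@cellData) != ncol(object@rna))
        msg <- c(msg, "cellData rows must match the number of cells")
    if (length(object@peaks) != nrow(object@atac))
        msg <- c(msg, "peaks must match atac rows")
    if (length(object@tss) != nrow(object@rna))
        msg <- c(msg, "tss must match rna rows")
    if (is.null(names(object@peaks)) || anyDuplicated(names(object@peaks)))
        msg <- c(msg, "peaks must carry unique names (peak ids)")
    if (is.null(names(object@tss)) || anyDuplicated(names(object@tss)))
        msg <- c(msg, "tss must carry unique names (gene ids)")
    gc <- mcols(object@peaks)$gc
    if (is.null(gc) || any(!is.finite(gc)) || any(gc < 0 | gc > 1))
        msg <- c(msg, "peaks must have a 'gc' metadata column in [0,1]")
    if (any(width(object@tss) != 1L))
        msg <- c(msg, "tss ranges must have width 1")
    cd <- object@cellData
    if (!all(c("subpop", "treatment") %in% colnames(cd)))
        msg <- c(msg, "cellData needs 'subpop' and 'treatment' columns")
    else if (!all(cd$treatment %in% c("unexposed", "oxldl")))
        msg <- c(msg, "treatment labels must be 'unexposed' or 'oxldl'")
    if (length(object@rna@x) && min(object@rna@x) < 0)
        msg <- c(msg, "rna counts must be non-negative")
    if (length(object@atac@x) && min(object@atac@x) < 0)
        msg <- c(msg, "atac counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a Multiome object
#'
#' @param rna gene x cell count matrix (coerced to sparse).
#' @param atac peak x cell count matrix (coerced to sparse).
#' @param peaks named \code{GRanges} of peaks with \code{gc} column.
#' @param tss named width-1 \code{GRanges} of gene TSS positions.
#' @param cellData \code{DataFrame} of per-cell labels.
#' @return a validated \linkS4class{Multiome}.
#' @examples
#' sim <- simulateMultiome(simMultiomeConfig(n_cells = 50, n_genes = 20,
#'     n_peaks = 100, seed = 1))
#' sim$multiome
#' @export
Multiome <- function(rna, atac, peaks, tss, cellData) {
    rna <- as(as(as(rna, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    atac <- as(as(as(atac, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    new("Multiome", rna = rna, atac = atac, peaks = peaks, tss = tss,
        cellData = as(cellData, "DataFrame"))
}

#' @describeIn Multiome-class gene x cell RNA counts
#' @param x a \code{Multiome}
#' @export
setMethod("rnaCounts", "Multiome", function(x) x@rna)

#' @describeIn Multiome-class peak x cell ATAC counts
#' @export
setMethod("atacCounts", "Multiome", function(x) x@atac)

#' @describeIn Multiome-class peak intervals
#' @export
setMethod("peakRanges", "Multiome", function(x) x@peaks)

#' @describeIn Multiome-class gene TSS positions
#' @export
setMethod("tssRanges", "Multiome", function(x) x@tss)

#' @describeIn Multiome-class per-cell metadata
#' @export
setMethod("cellInfo", "Multiome", function(x) x@cellData)

#' @describeIn Multiome-class number of cells
#' @export
setMethod("nCells", "Multiome", function(x) ncol(x@rna))

setMethod("show", "Multiome", function(object) {
    cat("Multiome object\n")
    cat(sprintf("  cells: %d | genes: %d | peaks: %d\n",
                ncol(object@rna), nrow(object@rna), nrow(object@atac)))
    cat(sprintf("  subpopulations: %s\n",
                paste(sort(unique(object@cellData$subpop)), collapse = ", ")))
    tr <- table(object@cellData$treatment)
    cat(sprintf("  treatment: %s\n",
                paste(names(tr), as.integer(tr), sep = "=", collapse = ", ")))
})

#' Reference haplotype panel with block LD structure
#'
#' Binary haplotypes (rows = haplotypes, columns = SNPs) organised in
#' independent LD blocks: SNPs in different blocks are generated
#' independently, so their population r-squared is zero by construction.
#'
#' @slot haplotypes 0/1 matrix, 2*n_ind rows x M SNP columns.
#' @slot snpTable \code{DataFrame}: snp_id, chrom, pos, a1, a2, maf, block.
#' @slot blockBounds integer vector of first-SNP indices per block.
#' @slot decay copy probability of the generating process (in [0,1));
#'   kept so GWAS cohorts can be drawn from the same process.
#' @seealso [simulateLDPanel()]
#' @export
setClass("LDPanel",
    slots = c(haplotypes = "matrix", snpTable = "DFrame",
              blockBounds = "integer", decay = "numeric"),
    prototype = list(decay = 0))

setValidity("LDPanel", function(object) {
    msg <- character()
    H <- object@haplotypes
    if (ncol(H) != nrow(object@snpTable))
        msg <- c(msg, "haplotype columns must match snpTable rows")
    if (nrow(H) < 4L || nrow(H) %% 2L != 0L)
        msg <- c(msg, "need an even number (>= 4) of haplotypes")
    if (length(H) && !all(H %in% c(0L, 1L)))
        msg <- c(msg, "haplotypes must be 0/1")
    maf <- object@snpTable$maf
    if (any(maf <= 0 | maf > 0.5))
        msg <- c(msg, "maf must lie in (0, 0.5]")
    if (length(object@decay) != 1L || object@decay < 0 || object@decay >= 1)
        msg <- c(msg, "decay must be a single value in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn LDPanel-class haplotype matrix
#' @param x an \code{LDPanel}
#' @export
setMethod("haplotypes", "LDPanel", function(x) x@haplotypes)

#' @describeIn LDPanel-class SNP table
#' @export
setMethod("snpInfo", "LDPanel", function(x) x@snpTable)

#' @describeIn LDPanel-class indices delimiting LD blocks
#' @export
setMethod("blockBounds", "LDPanel", function(x) x@blockBounds)

setMethod("show", "LDPanel", function(object) {
    cat("LDPanel\n")
    cat(sprintf("  haplotypes: %d (%d individuals) | SNPs: %d | blocks: %d\n",
                nrow(object@haplotypes), nrow(object@haplotypes) %/% 2L,
                ncol(object@haplotypes), length(object@blockBounds)))
})

#' Per-cell TF motif deviation scores
#'
#' Raw deviations are (observed - expected)/expected aggregate
#' accessibility over a TF's motif-bearing peaks; z scores are corrected
#' against GC/accessibility-matched background peak sets.
#'
#' @slot raw TF x cell matrix of raw deviations.
#' @slot z TF x cell matrix of background-corrected deviation z scores.
#' @seealso [computeDeviations()]
#' @export
setClass("MotifDeviations", slots = c(raw = "matrix", z = "matrix"))

setValidity("MotifDeviations", function(object) {
    if (!identical(dim(object@raw), dim(object@z)))
        return("raw and z must have identical dimensions")
    if (any(!is.finite(object@raw)))
        return("raw deviations must be finite")
    TRUE
})

#' @describeIn MotifDeviations-class extract deviation matrices
#' @param x a \code{MotifDeviations}
#' @param type \code{"z"} (background-corrected) or \code{"raw"}
#' @export
setMethod("deviationScores", "MotifDeviations", function(x,
        type = c("z", "raw")) {
    type <- match.arg(type)
    if (type == "z") x@z else x@raw
})

setMethod("show", "MotifDeviations", function(object) {
    cat(sprintf("MotifDeviations: %d TFs x %d cells\n",
                nrow(object@z), ncol(object@z)))
})

#' Stratified LD-score regression fit
#'
#' Result of regressing GWAS chi-squared statistics on annotation-
#' stratified LD scores: per-annotation coefficients tau with block-
#' jackknife standard errors, heritability enrichment, standardized
#' effect sizes tau-star, and the global heritability and intercept.
#'
#' @slot coefficients \code{DataFrame}, one row per annotation.
#' @slot h2 total SNP heritability estimate.
#' @slot intercept regression intercept (1 under no confounding).
#' @slot M number of SNPs in the regression.
#' @slot nBlocks number of jackknife blocks.
#' @seealso [fitSldsc()]
#' @export
setClass("SldscFit",
    slots = c(coefficients = "DFrame", h2 = "numeric", intercept = "numeric",
              M = "integer", nBlocks = "integer"))

#' @describeIn SldscFit-class per-annotation coefficient table
#' @param x an \code{SldscFit}
#' @export
setMethod("sldscCoefs", "SldscFit", function(x) x@coefficients)

#' @describeIn SldscFit-class total heritability estimate
#' @export
setMethod("h2Estimate", "SldscFit", function(x) x@h2)

#' @describeIn SldscFit-class regression intercept
#' @export
setMethod("sldscIntercept", "SldscFit", function(x) x@intercept)

setMethod("show", "SldscFit", function(object) {
    cat(sprintf("SldscFit: M=%d SNPs, %d annotations, %d jackknife blocks\n",
                object@M, nrow(object@coefficients), object@nBlocks))
    cat(sprintf("  h2 = %.4f | intercept = %.4f\n",
                object@h2, object@intercept))
    df <- as.data.frame(object@coefficients)
    print(df, digits = 3)
})
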