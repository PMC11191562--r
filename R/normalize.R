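#' Depth-normalize counts and log-transform
#'
#' Scales each cell (column) to a common total of \code{scale}, then
#' applies \code{log1p}. Used identically for RNA and ATAC modalities.
#'
#' @param counts feature x cell matrix of non-negative counts (sparse or
#'   dense).
#' @param scale target per-cell total (default 1e4).
#' @return a matrix of the same class/shape with normalized values.
#' @examples
#' m <- Matrix::Matrix(c(2, 0, 2, 1, 0, 1), nrow = 3, sparse = TRUE)
#' normalizeCounts(m, scale = 4)
#' @export
normalizeCounts <- function(counts, scale = 1e4) {
    if (min(counts) < 0)
        stop("counts must be non-negative")
    .assertPositive(scale, "scale")
    depth <- colSums(counts)
    if (any(depth == 0)) {
        bad <- which(depth == 0)
        nm <- if (!is.null(colnames(counts))) colnames(counts)[bad[1L]]
              else as.character(bad[1L])
        stop("cell '", nm, "' has zero total counts")
    }
    if (inherits(counts, "sparseMatrix")) {
        out <- counts %*% Diagonal(x = scale / depth)
        out@x <- log1p(out@x)
        dimnames(out) <- dimnames(counts)
        as(as(out, "generalMatrix"), "CsparseMatrix")
    } else {
        log1p(sweep(counts, 2L, depth, "/") * scale)
    }
}

#' Per-peak matching features: GC fraction and mean accessibility
#'
#' @param multiome a \linkS4class{Multiome}.
#' @param scale normalization scale passed to [normalizeCounts()].
#' @return \code{DataFrame} with columns peak_id, gc, mean_access (mean
#'   normalized accessibility across cells), one row per peak.
#' @examples
#' sim <- simulateMultiome(simMultiomeConfig(n_cells = 60, n_genes = 30,
#'     n_peaks = 150, seed = 1))
#' head(peakFeatures(sim$multiome))
#' @export
peakFeatures <- function(multiome, scale = 1e4) {
    stopifnot(is(multiome, "Multiome"))
    atacN <- normalizeCounts(atacCounts(multiome), scale = scale)
    DataFrame(peak_id = names(peakRanges(multiome)),
              gc = mcols(peakRanges(multiome))$gc,
              mean_access = unname(rowMeans(atacN)))
}

#' Background peaks matched on GC and mean accessibility
#'
#' Returns the \code{k} nearest peaks to \code{target} in the 2-D space
#' of standardized GC fraction and standardized \code{log1p} mean
#' accessibility, excluding the target itself. Deterministic given the
#' feature table; distance ties are broken by ascending peak index.
#'
#' @param features a peak feature table from [peakFeatures()] (columns
#'   peak_id, gc, mean_access).
#' @param target peak id (or index) of the peak to match.
#' @param k number of background peaks to return (< number of peaks).
#' @return character vector of k matched peak ids.
#' @examples
#' feats <- S4Vectors::DataFrame(peak_id = paste0("p", 1:10),
#'     gc = seq(0.3, 0.7, length.out = 10), mean_access = rep(1, 10))
#' matchBackgroundPeaks(feats, "p5", k = 3)
#' @export
matchBackgroundPeaks <- function(features, target, k) {
    k <- .assertCount(k, "k")
    if (is.character(target)) {
        target <- match(target, features$peak_id)
        if (is.na(target)) stop("target peak not found in features")
    }
    idx <- .matchAllPeaks(features, k, query = as.integer(target))
    features$peak_id[idx[1L, ]]
}
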