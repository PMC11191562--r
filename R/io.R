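#' Read a MatrixMarket count matrix with feature and barcode names
#'
#' @param mtx_path MatrixMarket coordinate file (1-based indices,
#'   features in rows).
#' @param features_path,barcodes_path one name per line (first TSV
#'   column used).
#' @return sparse feature x cell integer count matrix with dimnames.
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(3, 5),
#'     dims = c(2, 2), dimnames = list(c("f1", "f2"), c("c1", "c2")))
#' writeCounts(m, file.path(d, "m.mtx"), file.path(d, "f.tsv"),
#'     file.path(d, "b.tsv"))
#' readCounts(file.path(d, "m.mtx"), file.path(d, "f.tsv"),
#'     file.path(d, "b.tsv"))
#' @export
readCounts <- function(mtx_path, features_path, barcodes_path) {
    m <- readMM(mtx_path)
    feats <- read.delim(features_path, header = FALSE,
                        stringsAsFactors = FALSE)[, 1L]
    bcs <- read.delim(barcodes_path, header = FALSE,
                      stringsAsFactors = FALSE)[, 1L]
    if (nrow(m) != length(feats) || ncol(m) != length(bcs))
        stop("matrix dimensions ", nrow(m), "x", ncol(m),
             " do not match ", length(feats), " features / ",
             length(bcs), " barcodes")
    if (anyDuplicated(feats)) stop("duplicate feature names")
    if (anyDuplicated(bcs)) stop("duplicate barcode names")
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (length(m@x) && any(m@x != round(m@x)))
        stop("non-integer entries in ", mtx_path)
    if (length(m@x) && any(m@x < 0))
        stop("negative entries in ", mtx_path)
    dimnames(m) <- list(feats, bcs)
    m
}

#' Write a sparse count matrix as MatrixMarket + name files
#'
#' @param m feature x cell sparse matrix with dimnames.
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return invisibly, the mtx path.
#' @export
writeCounts <- function(m, mtx_path, features_path, barcodes_path) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("matrix must carry dimnames")
    writeMM(as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix"),
            mtx_path)
    writeLines(rownames(m), features_path)
    writeLines(colnames(m), barcodes_path)
    invisible(mtx_path)
}

#' Read ldsc-style GWAS summary statistics
#'
#' Expects a header with columns SNP, A1, A2, Z, N (tab-separated).
#' Rows with missing Z are dropped with a message; duplicate SNP ids are
#' an error; alleles must be A/C/G/T.
#'
#' @param path sumstats TSV.
#' @return \code{DataFrame} with snp, a1, a2, z, n, chi2.
#' @export
readSumstats <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
    need <- c("SNP", "A1", "A2", "Z", "N")
    if (!all(need %in% colnames(d)))
        stop("sumstats must have columns ", paste(need, collapse = " "))
    if (!all(d$A1 %in% c("A", "C", "G", "T")) ||
        !all(d$A2 %in% c("A", "C", "G", "T")))
        stop("alleles must be one of A, C, G, T")
    drop <- is.na(d$Z)
    if (any(drop))
        message(sum(drop), " rows with missing Z dropped")
    d <- d[!drop, , drop = FALSE]
    if (anyDuplicated(d$SNP)) stop("duplicated SNP ids in ", path)
    DataFrame(snp = d$SNP, a1 = d$A1, a2 = d$A2, z = as.numeric(d$Z),
              n = as.numeric(d$N), chi2 = as.numeric(d$Z)^2)
}

#' Write GWAS summary statistics in the ldsc dialect
#'
#' @param sumstats \code{DataFrame} with snp, a1, a2, z, n.
#' @param path output TSV (header SNP A1 A2 Z N).
#' @return invisibly, the path.
#' @export
writeSumstats <- function(sumstats, path) {
    d <- data.frame(SNP = sumstats$snp, A1 = sumstats$a1,
                    A2 = sumstats$a2, Z = sumstats$z, N = sumstats$n)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
    invisible(path)
}

#' Write a LinkTable as BED-plus TSV
#'
#' Columns: chrom, start, end (0-based half-open), peak_id, gene_id,
#' distance_bp, r_obs, z_link, p_link, fdr, is_cre, preceded by '#'
#' provenance comment lines.
#'
#' @param links LinkTable from [linkPeaksToGenes()].
#' @param path output path.
#' @param seed seed recorded in the header.
#' @return invisibly, the path.
#' @export
writeLinkTable <- function(links, path, seed = NA) {
    .writeTsv(as.data.frame(links), path,
              meta = c(sprintf("seed=%s", seed),
                       sprintf("checksum=%s", .checksum(as.data.frame(links)))))
}

#' Write a Multiome object to a directory of standard flat files
#'
#' Writes rna.mtx / atac.mtx with feature and barcode TSVs, peaks.bed
#' (BED4+: chrom, start, end, name, gc; 0-based half-open), tss.tsv
#' (gene, chrom, tss0, strand) and cells.tsv (cell, subpop, treatment).
#'
#' @param multiome a \linkS4class{Multiome}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeMultiome <- function(multiome, dir) {
    stopifnot(is(multiome, "Multiome"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCounts(rnaCounts(multiome), file.path(dir, "rna.mtx"),
                file.path(dir, "rna_features.tsv"),
                file.path(dir, "barcodes.tsv"))
    writeCounts(atacCounts(multiome), file.path(dir, "atac.mtx"),
                file.path(dir, "atac_features.tsv"),
                file.path(dir, "barcodes.tsv"))
    pk <- peakRanges(multiome)
    bed <- data.frame(chrom = as.character(seqnames(pk)),
                      start = start(pk) - 1L, end = end(pk),
                      name = names(pk), gc = mcols(pk)$gc)
    write.table(bed, file.path(dir, "peaks.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    ts <- tssRanges(multiome)
    tssTab <- data.frame(gene = names(ts),
                         chrom = as.character(seqnames(ts)),
                         tss0 = start(ts) - 1L,
                         strand = as.character(strand(ts)))
    write.table(tssTab, file.path(dir, "tss.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(cellInfo(multiome))
    cd <- cbind(cell = rownames(cd), cd)
    write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a Multiome object written by [writeMultiome()]
#'
#' @param dir directory containing the flat files.
#' @return a \linkS4class{Multiome}.
#' @export
readMultiome <- function(dir) {
    rna <- readCounts(file.path(dir, "rna.mtx"),
                      file.path(dir, "rna_features.tsv"),
                      file.path(dir, "barcodes.tsv"))
    atac <- readCounts(file.path(dir, "atac.mtx"),
                       file.path(dir, "atac_features.tsv"),
                       file.path(dir, "barcodes.tsv"))
    bed <- read.delim(file.path(dir, "peaks.bed"), header = FALSE,
                      col.names = c("chrom", "start", "end", "name", "gc"))
    peaks <- GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end))
    names(peaks) <- bed$name
    mcols(peaks)$gc <- bed$gc
    tssTab <- read.delim(file.path(dir, "tss.tsv"))
    tss <- GRanges(tssTab$chrom, IRanges(tssTab$tss0 + 1L, width = 1L),
                   strand = tssTab$strand)
    names(tss) <- tssTab$gene
    cd <- read.delim(file.path(dir, "cells.tsv"))
    Multiome(rna, atac, peaks, tss,
             DataFrame(subpop = cd$subpop, treatment = cd$treatment,
                       row.names = cd$cell))
}
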