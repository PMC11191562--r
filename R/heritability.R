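#' Differential expression statistics by Wilcoxon rank-sum test
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two cell groups on
#' the normalized expression matrix, with a Seurat-style log2 fold change
#' of back-transformed group means (pseudocount 1) and a BH-FDR.
#'
#' @param rna normalized (log1p) gene x cell matrix.
#' @param labels character/factor label per cell.
#' @param contrast length-2 character: c(groupA, groupB); positive
#'   log2fc means higher in groupA.
#' @return \code{DataFrame}: gene, log2fc, p, fdr.
#' @examples
#' sim <- simulateMultiome(simMultiomeConfig(n_cells = 120, n_genes = 50,
#'     n_peaks = 100, seed = 1))
#' rnaN <- normalizeCounts(rnaCounts(sim$multiome))
#' de <- differentialStats(rnaN, cellInfo(sim$multiome)$treatment,
#'     c("oxldl", "unexposed"))
#' head(de)
#' @export
differentialStats <- function(rna, labels, contrast) {
    if (length(labels) != ncol(rna))
        stop("labels must have one entry per cell")
    if (length(contrast) != 2L)
        stop("contrast must name exactly two groups")
    a <- which(labels == contrast[1L])
    b <- which(labels == contrast[2L])
    if (length(a) < 3L || length(b) < 3L)
        stop("each contrast group needs at least 3 cells")
    rna <- as.matrix(rna)
    genes <- rownames(rna)
    p <- numeric(nrow(rna))
    for (i in seq_len(nrow(rna))) {
        xa <- rna[i, a]; xb <- rna[i, b]
        if (sd(c(xa, xb)) == 0) { p[i] <- 1; next }
        p[i] <- suppressWarnings(
            wilcox.test(xa, xb, exact = FALSE)$p.value)
    }
    p[is.na(p)] <- 1
    mA <- rowMeans(expm1(rna[, a, drop = FALSE]))
    mB <- rowMeans(expm1(rna[, b, drop = FALSE]))
    DataFrame(gene = genes,
              log2fc = log2(mA + 1) - log2(mB + 1),
              p = p,
              fdr = p.adjust(p, method = "BH"))
}

#' Build a weighted gene program from differential expression statistics
#'
#' Weighted mode: \code{w_g = min(-log10 fdr, cap)/cap} for up-regulated
#' genes (log2fc > 0), 0 otherwise, giving weights in [0,1] saturating at
#' \code{fdr = 10^-cap}. Binary mode: \code{w_g = 1} iff \code{fdr <
#' 0.05} and \code{log2fc > 0}.
#'
#' @param de \code{DataFrame} from [differentialStats()].
#' @param mode \code{"weighted"} (default) or \code{"binary"}.
#' @param cap saturation exponent for weighted mode (default 10).
#' @return named numeric vector of weights in [0,1] (a gene program).
#' @examples
#' de <- S4Vectors::DataFrame(gene = c("g1", "g2", "g3"),
#'     log2fc = c(2, 2, -1), p = c(1e-6, 0.5, 1e-8),
#'     fdr = c(1e-5, 0.6, 1e-8))
#' buildGeneProgram(de)
#' @export
buildGeneProgram <- function(de, mode = c("weighted", "binary"), cap = 10) {
    mode <- match.arg(mode)
    .assertPositive(cap, "cap")
    if (!all(c("gene", "log2fc", "fdr") %in% colnames(de)))
        stop("de needs columns gene, log2fc, fdr")
    up <- de$log2fc > 0
    w <- if (mode == "weighted")
        ifelse(up, pmin(-log10(pmax(de$fdr, 1e-300)), cap) / cap, 0)
    else as.numeric(up & de$fdr < 0.05)
    if (all(w == 0))
        stop("gene program has no positive weights")
    setNames(w, de$gene)
}

#' Convert a gene program into a per-SNP annotation via the CRE map
#'
#' Every CRE of a program gene carries that gene's weight; a SNP
#' overlapping several weighted CREs takes the maximum weight (so
#' overlapping CREs of one gene do not inflate it); SNPs overlapping
#' nothing get 0. Containment follows the 0-based half-open convention
#' with 1-based SNP input positions. Program genes without CREs
#' contribute nothing (reported via a message).
#'
#' @param program named weight vector from [buildGeneProgram()].
#' @param links LinkTable from [linkPeaksToGenes()].
#' @param snp_positions table with snp_id, chrom, pos (1-based), e.g.
#'   from [placeSnps()].
#' @return named numeric vector a(j) over the SNPs, in input order.
#' @export
programToAnnotation <- function(program, links, snp_positions) {
    sp <- as.data.frame(snp_positions)
    if (!all(c("snp_id", "chrom", "pos") %in% colnames(sp)))
        stop("snp_positions needs snp_id, chrom, pos")
    w <- program[program > 0]
    cre <- links[links$is_cre & links$gene_id %in% names(w), , drop = FALSE]
    noCre <- setdiff(names(w), cre$gene_id)
    if (length(noCre))
        message(length(noCre), " program gene(s) without CREs contribute ",
                "no SNP weight")
    ann <- setNames(numeric(nrow(sp)), sp$snp_id)
    if (!nrow(cre)) return(ann)
    if (!any(sp$chrom %in% cre$chrom))
        stop("SNP and CRE coordinate namespaces do not overlap ",
             "(chromosome mismatch)")
    snpGR <- GRanges(sp$chrom, IRanges(sp$pos, width = 1L))
    creGR <- GRanges(cre$chrom, IRanges(cre$peak_start + 1L, cre$peak_end))
    ov <- findOverlaps(snpGR, creGR)
    if (length(ov)) {
        wts <- unname(w[cre$gene_id[S4Vectors::subjectHits(ov)]])
        agg <- tapply(wts, S4Vectors::queryHits(ov), max)
        ann[as.integer(names(agg))] <- as.numeric(agg)
    }
    ann
}

#' Annotation-stratified LD scores from a haplotype panel
#'
#' \code{l(j,c) = sum_k r2adj_jk * a_c(k)} over SNPs k within
#' \code{window_bp} of SNP j (including k = j), with the bias-adjusted
#' \code{r2adj = r2 - (1 - r2)/(n - 2)} where n is the number of
#' haplotypes. Sample correlations are used for all in-window pairs, so
#' the vectorized result matches a brute-force double loop exactly.
#'
#' @param panel an \linkS4class{LDPanel}.
#' @param annotations M x C matrix of annotation values (vector = one
#'   annotation); rownames ignored, order must match the panel SNPs.
#' @param window_bp window radius in bp (default 1e6).
#' @return M x C matrix of LD scores, rownames = SNP ids.
#' @examples
#' panel <- simulateLDPanel(100, 2, 10, decay = 0.9, seed = 1)
#' l <- computeLdScores(panel, matrix(1, 20, 1))
#' head(l)
#' @export
computeLdScores <- function(panel, annotations, window_bp = 1e6) {
    stopifnot(is(panel, "LDPanel"))
    if (window_bp < 0) stop("window_bp must be non-negative")
    H <- panel@haplotypes
    n <- nrow(H)
    M <- ncol(H)
    ann <- as.matrix(annotations)
    if (nrow(ann) != M)
        stop("annotations must have one row per panel SNP")
    pos <- panel@snpTable$pos
    Hs <- scale(H)
    out <- matrix(0, M, ncol(ann),
                  dimnames = list(panel@snpTable$snp_id, colnames(ann)))
    chunk <- 500L
    for (s in seq(1L, M, by = chunk)) {
        J <- s:min(s + chunk - 1L, M)
        lo <- findInterval(pos[J[1L]] - window_bp - 0.5, pos) + 1L
        hi <- findInterval(pos[J[length(J)]] + window_bp + 0.5, pos)
        K <- lo:hi
        r <- crossprod(Hs[, J, drop = FALSE], Hs[, K, drop = FALSE]) /
            (n - 1)
        r2 <- r^2
        r2 <- r2 - (1 - r2) / (n - 2)
        r2[abs(outer(pos[J], pos[K], "-")) > window_bp] <- 0
        out[J, ] <- r2 %*% ann[K, , drop = FALSE]
    }
    out
}

# delete-one-block jackknife: X (M x p), y, w; blocks = integer block id
# per row. Returns list(est, reps (B x p))
.jackknifeWls <- function(X, y, w, blocks) {
    Xw <- X * w
    XtX <- crossprod(Xw, X)
    Xty <- crossprod(Xw, y)
    B <- max(blocks)
    p <- ncol(X)
    est <- solve(XtX, Xty)
    reps <- matrix(0, B, p)
    for (b in seq_len(B)) {
        sel <- blocks == b
        Xb <- X[sel, , drop = FALSE]
        Xwb <- Xw[sel, , drop = FALSE]
        reps[b, ] <- solve(XtX - crossprod(Xwb, Xb),
                           Xty - crossprod(Xwb, y[sel]))
    }
    list(est = as.vector(est), reps = reps)
}

.jackSe <- function(reps) {
    B <- nrow(reps)
    ctr <- sweep(reps, 2L, colMeans(reps))
    sqrt((B - 1) / B * colSums(ctr^2))
}

#' Stratified LD-score regression
#'
#' Weighted least squares of GWAS chi-squared statistics on \code{N *
#' l(j,c)} with a free intercept. Initial weights \code{1/max(l_base,1)}
#' are refined once by the heteroscedasticity factor \code{1/(2 *
#' (intercept + N * sum_c tau_c l(j,c))^2)} from the first pass.
#' Standard errors come from a delete-one block jackknife over
#' \code{n_blocks} contiguous SNP blocks. Reports, per annotation: tau,
#' its SE, the heritability share, enrichment (share of h2 over share of
#' SNPs; exactly 1 for the all-SNP base annotation), the standardized
#' effect size \code{tau* = tau * sd_j(a_c) * M / h2}, and the jackknife
#' p-value for tau*.
#'
#' @param sumstats \code{DataFrame} with snp, z (or chi2) and n, e.g.
#'   from [simulateSumstats()] or [readSumstats()].
#' @param ld M x C LD-score matrix from [computeLdScores()], rownames =
#'   SNP ids; must include a column named \code{"base"}.
#' @param annotations M x C annotation matrix (same columns as
#'   \code{ld}) used for h2 shares, enrichment and sd(a_c).
#' @param n_blocks jackknife blocks (default \code{min(200, M/25)}).
#' @return an \linkS4class{SldscFit}.
#' @examples
#' panel <- simulateLDPanel(100, 20, 25, decay = 0.9, seed = 1)
#' M <- 500
#' ann <- cbind(base = rep(1, M), targ = rep(c(1, 0), c(100, 400)))
#' tau <- c(0.1 / M, 0.1 / 100)
#' ss <- simulateSumstats(panel, ann, tau, n_gwas = 2000, seed = 2)
#' ld <- computeLdScores(panel, ann, window_bp = 5e4)
#' fitSldsc(ss, ld, ann)
#' @export
fitSldsc <- function(sumstats, ld, annotations, n_blocks = NULL) {
    ann <- as.matrix(annotations)
    ld <- as.matrix(ld)
    if (is.null(colnames(ld))) stop("ld must have annotation colnames")
    if (!"base" %in% colnames(ld))
        stop("ld must include a 'base' annotation column")
    if (!identical(colnames(ld), colnames(ann)))
        stop("ld and annotations must have identical columns")
    ss <- as.data.frame(sumstats)
    if (is.null(rownames(ld)))
        stop("ld must carry SNP rownames")
    m <- match(rownames(ld), ss$snp)
    if (all(is.na(m))) stop("no SNPs shared between sumstats and ld")
    keep <- !is.na(m)
    ld <- ld[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]
    ss <- ss[m[keep], , drop = FALSE]
    M <- nrow(ld)
    chi2 <- if ("chi2" %in% colnames(ss)) ss$chi2 else ss$z^2
    N <- ss$n
    if (is.null(n_blocks)) n_blocks <- max(2L, min(200L, M %/% 25L))
    n_blocks <- .assertCount(n_blocks, "n_blocks", min = 2L)

    X <- cbind(intercept = 1, N * ld)
    if (qr(X)$rank < ncol(X))
        stop("collinear annotation design: LD-score columns are linearly ",
             "dependent")
    w1 <- 1 / pmax(ld[, "base"], 1)
    Xw1 <- X * w1
    fit1 <- as.vector(solve(crossprod(Xw1, X), crossprod(Xw1, chi2)))
    fitted <- pmax(as.vector(X %*% fit1), 0.05)
    w <- w1 / (2 * fitted^2)

    blocks <- as.integer(cut(seq_len(M), breaks = n_blocks, labels = FALSE))
    jk <- .jackknifeWls(X, chi2, w, blocks)
    coefs <- jk$est
    intercept <- coefs[1L]
    tau <- coefs[-1L]
    names(tau) <- colnames(ld)

    annSum <- colSums(ann)
    sdAnn <- apply(ann, 2L, sd)
    statFun <- function(tauv) {
        h2 <- sum(tauv * annSum)
        sigma2 <- as.vector(ann %*% tauv)
        propH2 <- as.vector(crossprod(ann, sigma2)) / h2
        enr <- propH2 / (annSum / M)
        tstar <- tauv * sdAnn * M / h2
        c(h2, enr, tstar)
    }
    full <- statFun(tau)
    C <- ncol(ld)
    h2 <- full[1L]
    enrich <- full[1L + seq_len(C)]
    tauStar <- full[1L + C + seq_len(C)]

    repsStat <- t(apply(jk$reps[, -1L, drop = FALSE], 1L, statFun))
    seTau <- .jackSe(jk$reps)[-1L]
    seH2 <- .jackSe(repsStat[, 1L, drop = FALSE])
    seEnrich <- .jackSe(repsStat[, 1L + seq_len(C), drop = FALSE])
    seTauStar <- .jackSe(repsStat[, 1L + C + seq_len(C), drop = FALSE])
    seInt <- .jackSe(jk$reps)[1L]

    degenerate <- sdAnn == 0
    tauStar[degenerate] <- NA_real_
    seTauStar[degenerate] <- NA_real_
    if (h2 < 0) {
        warning("negative h2 estimate; tau* suppressed")
        tauStar[] <- NA_real_
    }
    pTauStar <- 2 * pnorm(-abs(tauStar / seTauStar))

    coefTab <- DataFrame(
        annotation = colnames(ld),
        tau = unname(tau), se_tau = unname(seTau),
        prop_snps = unname(annSum / M),
        prop_h2 = unname(as.vector(crossprod(ann, as.vector(ann %*% tau)))
                         / h2),
        enrichment = unname(enrich), se_enrichment = unname(seEnrich),
        tau_star = unname(tauStar), se_tau_star = unname(seTauStar),
        p_tau_star = unname(pTauStar))
    metadata(coefTab) <- list(h2_se = seH2, intercept_se = seInt)
    new("SldscFit", coefficients = coefTab, h2 = h2,
        intercept = intercept, M = as.integer(M),
        nBlocks = as.integer(n_blocks))
}

#' Conditional standardized effect sizes from a joint S-LDSC fit
#'
#' Fits a single joint stratified LD-score regression including the base
#' (all-SNP) annotation, an optional background annotation (e.g. all
#' open-chromatin SNPs), and all listed program annotations, then
#' reports each program's tau* from the joint coefficients -- i.e. each
#' program's effect conditional on the others and on the background.
#'
#' @param sumstats summary statistics (see [fitSldsc()]).
#' @param panel an \linkS4class{LDPanel} used to compute LD scores.
#' @param programs named list (or M x K matrix) of per-SNP program
#'   annotation vectors.
#' @param background optional per-SNP background annotation vector.
#' @param window_bp LD-score window (default 1e6).
#' @param n_blocks jackknife blocks (default as in [fitSldsc()]).
#' @return list with \code{fit} (the joint \linkS4class{SldscFit}) and
#'   \code{tau_star} (\code{DataFrame} restricted to the program rows).
#' @export
conditionalTauStar <- function(sumstats, panel, programs,
                               background = NULL, window_bp = 1e6,
                               n_blocks = NULL) {
    stopifnot(is(panel, "LDPanel"))
    progs <- if (is.list(programs)) do.call(cbind, programs)
             else as.matrix(programs)
    if (is.null(colnames(progs)))
        colnames(progs) <- paste0("program", seq_len(ncol(progs)))
    M <- ncol(panel@haplotypes)
    ann <- cbind(base = rep(1, M))
    if (!is.null(background)) ann <- cbind(ann, background = background)
    ann <- cbind(ann, progs)
    ld <- computeLdScores(panel, ann, window_bp = window_bp)
    fit <- fitSldsc(sumstats, ld, ann, n_blocks = n_blocks)
    tab <- sldscCoefs(fit)
    list(fit = fit,
         tau_star = tab[tab$annotation %in% colnames(progs), , drop = FALSE])
}
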