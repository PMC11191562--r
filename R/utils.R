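# Internal helpers shared across modules.

.assertCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < min)
        stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
    as.integer(x)
}

.assertFraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop("'", name, "' must be a single value in [0, 1]", call. = FALSE)
    as.numeric(x)
}

.assertPositive <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
        stop("'", name, "' must be a single positive number", call. = FALSE)
    as.numeric(x)
}

# z-standardize; constant vectors map to all-zero rather than NaN
.stdize <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
}

.rowSds <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

# Row-standardize a dense matrix (rows = features, cols = cells).
# Rows with zero variance become all-zero and are flagged.
.rowStandardize <- function(m) {
    mu <- rowMeans(m)
    s <- .rowSds(m)
    bad <- !is.finite(s) | s == 0
    s[bad] <- 1
    out <- (m - mu) / s
    out[bad, ] <- 0
    list(mat = out, constant = bad)
}

# k nearest peaks per peak in the standardized (gc, log1p mean accessibility)
# plane; ties broken by ascending peak index; self excluded.
# `candidates`: indices allowed as matches (default all). Returns an
# n_query x k integer matrix of indices into `features` rows.
.matchAllPeaks <- function(features, k, query = seq_len(nrow(features)),
                           candidates = seq_len(nrow(features))) {
    n <- nrow(features)
    if (anyDuplicated(features$peak_id))
        stop("duplicate peak_ids in peak features", call. = FALSE)
    if (k >= length(candidates))
        stop("k must be smaller than the number of candidate peaks",
             call. = FALSE)
    gcz <- .stdize(features$gc)
    az <- .stdize(log1p(features$mean_access))
    out <- matrix(NA_integer_, nrow = length(query), ncol = k)
    for (i in seq_along(query)) {
        q <- query[i]
        d2 <- (gcz[candidates] - gcz[q])^2 + (az[candidates] - az[q])^2
        d2[candidates == q] <- Inf
        ord <- order(d2, candidates)
        out[i, ] <- candidates[ord[seq_len(k)]]
    }
    out
}

# Spearman rho between rows of X and rows of Y (columns = cells).
.spearmanRho <- function(X, Y) {
    rx <- t(apply(X, 1L, rank))
    ry <- t(apply(Y, 1L, rank))
    sx <- .rowStandardize(rx)
    sy <- .rowStandardize(ry)
    n <- ncol(X)
    rho <- tcrossprod(sx$mat, sy$mat) / (n - 1)
    rho[sx$constant, ] <- NA_real_
    rho[, sy$constant] <- NA_real_
    rho
}

# two-sided p-value for a Pearson/Spearman correlation via the t reference
.corTestP <- function(r, n) {
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
}

# cheap content checksum for output provenance headers (not cryptographic)
.checksum <- function(x) {
    raw <- serialize(x, NULL, version = 2L)
    raw <- head(raw, 65536L)
    v <- as.integer(raw)
    sprintf("%08x", sum(v * (seq_along(v) %% 97L + 1L)) %% .Machine$integer.max)
}

# TSV writer with provenance comment header ('#' lines), '.' for NA, LF
.writeTsv <- function(df, path, meta = character()) {
    meta <- c(sprintf("macroCRE %s", as.character(packageVersion("macroCRE"))),
              meta)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste0("# ", meta), con, sep = "\n")
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
        if (is.list(df[[j]]))
            df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    }
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".", eol = "\n")
    invisible(path)
}

.readTsv <- function(path) {
    read.delim(path, comment.char = "#", na.strings = ".",
               stringsAsFactors = FALSE)
}
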