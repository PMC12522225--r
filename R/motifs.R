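#' Enumerate k-mer end motifs in lexicographic order
#'
#' The motif axis of every matrix in the pipeline: all \eqn{4^k} DNA k-mers
#' over \{A, C, G, T\}, lexicographically ordered, so `AAAA` has index 1 and
#' `TTTT` index 256 for k = 4.
#'
#' @param k motif length in bases, between 1 and 8
#' @return character vector of length \eqn{4^k}
#' @examples
#' enumerateMotifs(1)          # "A" "C" "G" "T"
#' head(enumerateMotifs(4), 2) # "AAAA" "AAAC"
#' @export
enumerateMotifs <- function(k = 4L) {
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 8 || k != round(k))
        stop("k must be a single integer in 1..8")
    bases <- c("A", "C", "G", "T")
    grid <- expand.grid(rev(replicate(k, bases, simplify = FALSE)),
                        stringsAsFactors = FALSE)
    ## expand.grid varies the first factor fastest; reversed columns give
    ## lexicographic order when pasted back left-to-right
    sort(do.call(paste0, rev(grid)))
}

#' Convert end-motif counts to ratio-to-average values
#'
#' For each sample, each motif count is divided by the mean count over all
#' 256 motifs: \eqn{r_m = c_m / (\sum_m c_m / 256)}.  Every usable sample's
#' ratio profile therefore averages exactly 1 (sums to 256).  Samples with a
#' zero total are left as NA in the ratio assay and reported by a warning --
#' they are never silently converted.
#'
#' @param x a [MotifExperiment-class] with a `counts` assay
#' @return `x` with a `ratio` assay added and a logical
#'   `zero_total` column in `colData`
#' @export
countsToRatios <- function(x) {
    stopifnot(is(x, "MotifExperiment"))
    cnt <- motifCounts(x)
    tot <- colSums(cnt)
    ratio <- sweep(cnt, 2, tot / nrow(cnt), "/")
    if (any(tot == 0)) {
        ratio[, tot == 0] <- NA_real_
        warning(sum(tot == 0), " sample(s) with zero usable fragments ",
                "excluded from ratio conversion: ",
                paste(colnames(cnt)[tot == 0], collapse = ", "))
    }
    SummarizedExperiment::assay(x, "ratio") <- ratio
    x$zero_total <- tot == 0
    x
}

#' Fit per-motif Z-score statistics on a designated sample set
#'
#' Computes each motif's mean and sample standard deviation (n - 1
#' denominator) of the ratio values over the fitting samples -- normally the
#' training split, so that validation/test standardisation reuses frozen
#' training statistics.  Zero-variance motifs are recorded as constant.
#'
#' @param x a [MotifExperiment-class] with a `ratio` assay
#' @param fittingIds character vector of sample (column) names to fit on;
#'   at least 2
#' @return a [ScalerStats-class]
#' @export
fitZscore <- function(x, fittingIds = colnames(x)) {
    stopifnot(is(x, "MotifExperiment"))
    bad <- setdiff(fittingIds, colnames(x))
    if (length(bad)) stop("unknown fitting sample(s): ",
                          paste(head(bad, 5), collapse = ", "))
    if (length(fittingIds) < 2L) stop("need at least 2 fitting samples")
    r <- motifRatios(x)[, fittingIds, drop = FALSE]
    if (anyNA(r)) stop("fitting set contains zero-total samples")
    mu <- rowMeans(r)
    sdv <- apply(r, 1, sd)
    new("ScalerStats", mean = mu, sd = sdv,
        constant = rownames(r)[sdv == 0],
        nFit = length(fittingIds))
}

#' Apply frozen Z-score statistics to an end-motif ratio matrix
#'
#' Standardises each motif as \eqn{z = (r - \mu) / \sigma} with the
#' fitted statistics.  Constant motifs (sd = 0 on the fitting set) are
#' mapped to z = 0 rather than dropped, keeping the fixed 256-column
#' geometry expected by PCA; their names are recorded in
#' `metadata(x)$constant_motifs`.
#'
#' @param x a [MotifExperiment-class] with a `ratio` assay
#' @param stats a [ScalerStats-class] fitted on the same motif ordering
#' @return `x` with a `zscore` assay added
#' @export
applyZscore <- function(x, stats) {
    stopifnot(is(x, "MotifExperiment"), is(stats, "ScalerStats"))
    r <- motifRatios(x)
    if (!identical(rownames(r), names(stats@mean)))
        stop("motif axis mismatch between matrix and ScalerStats")
    sdv <- stats@sd
    safe <- ifelse(sdv == 0, 1, sdv)
    z <- (r - stats@mean) / safe
    z[sdv == 0, ] <- 0
    SummarizedExperiment::assay(x, "zscore") <- z
    S4Vectors::metadata(x)$constant_motifs <- stats@constant
    x
}

#' Write / read an end-motif matrix as TSV
#'
#' Samples in rows, the 256 lexicographic motifs as columns, a `sample_id`
#' first column.
#'
#' @param x a [MotifExperiment-class]
#' @param file path to write to / read from
#' @param assay which assay to export
#' @return `writeMotifTSV` returns `file` invisibly; `readMotifTSV` returns
#'   a [MotifExperiment-class] (counts assay).
#' @export
writeMotifTSV <- function(x, file, assay = "counts") {
    m <- t(SummarizedExperiment::assay(x, assay))
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeMotifTSV
#' @export
readMotifTSV <- function(file) {
    df <- read.delim(file, check.names = FALSE)
    m <- as.matrix(df[, enumerateMotifs(4L)])
    rownames(m) <- df$sample_id
    MotifExperiment(m)
}
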