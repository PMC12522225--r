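#' Per-feature two-sample differential t-tests
#'
#' Compares cases (ESCC and precancerous samples pooled) against controls
#' feature by feature with a two-sample t-test -- Student's pooled-variance
#' test by default, Welch optionally -- and selects features at a raw
#' two-sided p < `alpha`.  No multiple-testing correction is applied by
#' default, matching the screening pipeline's raw-p filter; Benjamini-
#' Hochberg selection on the FDR is available via `correct = "BH"`.
#' Features with zero variance in both classes have an undefined t; they
#' are reported unselected with flag `"zero_variance"` (t = 0, p = 1).
#'
#' @param x samples x features numeric matrix (or data.frame)
#' @param labels case/control labels: logical (TRUE = case), or a factor /
#'   character with `"control"` as the control level
#' @param alpha selection threshold (default 0.05)
#' @param variance `"equal"` (Student, default) or `"unequal"` (Welch)
#' @param correct `"none"` (default) or `"BH"`
#' @return a [DifferentialResult-class]; direction is `"up"` exactly when
#'   the case-minus-control mean difference is positive
#' @export
ttestDifferential <- function(x, labels, alpha = 0.05,
                              variance = c("equal", "unequal"),
                              correct = c("none", "BH")) {
    variance <- match.arg(variance)
    correct <- match.arg(correct)
    x <- as.matrix(x)
    case <- isCase(labels)
    if (length(case) != nrow(x))
        stop("labels must cover all ", nrow(x), " rows")
    n1 <- sum(case); n0 <- sum(!case)
    if (n1 < 2L || n0 < 2L)
        stop("need at least 2 samples per class (got ", n1, " cases, ",
             n0, " controls)")
    xc <- x[case, , drop = FALSE]
    x0 <- x[!case, , drop = FALSE]
    m1 <- colMeans(xc); m0 <- colMeans(x0)
    v1 <- apply(xc, 2, var); v0 <- apply(x0, 2, var)
    d <- m1 - m0
    if (variance == "equal") {
        sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n0))
        df <- rep(n1 + n0 - 2, length(d))
    } else {
        se <- sqrt(v1 / n1 + v0 / n0)
        df <- (v1 / n1 + v0 / n0)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    }
    zero <- se == 0
    t <- ifelse(zero, 0, d / ifelse(zero, 1, se))
    p <- ifelse(zero, 1, 2 * pt(-abs(t), df))
    pSel <- if (correct == "BH") stats::p.adjust(p, "BH") else p
    feat <- colnames(x)
    if (is.null(feat)) feat <- sprintf("f%03d", seq_along(d))
    tab <- data.frame(
        feature = feat, t = t, p = p,
        meanDiff = d,
        direction = ifelse(d > 0, "up", "down"),
        selected = !zero & pSel < alpha,
        flag = ifelse(zero, "zero_variance", ""),
        stringsAsFactors = FALSE, row.names = NULL)
    new("DifferentialResult", table = tab, alpha = alpha,
        variance = variance)
}

## normalise assorted label encodings to logical is-case
isCase <- function(labels) {
    if (is.logical(labels)) return(labels)
    l <- as.character(labels)
    if (all(l %in% c("case", "control"))) return(l == "case")
    if (any(l %in% groupLevels())) return(l != "control")
    stop("labels must be logical, case/control, or group levels")
}

#' Fit a principal component model on training data
#'
#' Eigendecomposition of the training covariance of the (already
#' Z-scored) selected-feature submatrix; components are ordered by
#' decreasing explained variance and each component's sign is fixed so its
#' largest-magnitude loading is positive, making the fit deterministic.
#' No additional scaling is applied beyond centring on training means.
#'
#' @param x training samples x features matrix
#' @param nComponents number of components to keep (default 30); must be
#'   at most `min(nrow(x) - 1, ncol(x))`
#' @return a [PCAModel-class]
#' @export
pcaFit <- function(x, nComponents = 30L) {
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("need at least 2 training samples")
    kmax <- min(nrow(x) - 1L, ncol(x))
    if (nComponents > kmax)
        stop("nComponents = ", nComponents, " exceeds min(n - 1, p) = ",
             kmax)
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    sv <- svd(xc, nu = 0)
    ev <- sv$d^2 / (nrow(x) - 1)         # covariance eigenvalues
    load <- sv$v[, seq_len(nComponents), drop = FALSE]
    ## deterministic sign: largest-|loading| entry positive per component
    for (j in seq_len(ncol(load))) {
        i <- which.max(abs(load[, j]))
        if (load[i, j] < 0) load[, j] <- -load[, j]
    }
    rownames(load) <- colnames(x)
    colnames(load) <- sprintf("PC%d", seq_len(ncol(load)))
    new("PCAModel", center = ctr, loadings = load,
        eigenvalues = ev[seq_len(nComponents)],
        varianceExplained = (ev / sum(ev))[seq_len(nComponents)])
}

#' Project samples onto a fitted principal component model
#'
#' Scores are `(row - training means) %*% loadings`; validation and test
#' rows reuse the training means, so no information flows back from them.
#'
#' @param x samples x features matrix on the model's feature axis
#' @param model a [PCAModel-class]
#' @return samples x components score matrix
#' @export
pcaTransform <- function(x, model) {
    x <- as.matrix(x)
    if (!is.null(colnames(x)) &&
        !identical(colnames(x), rownames(model@loadings)))
        stop("feature axis mismatch between data and PCAModel")
    if (ncol(x) != nrow(model@loadings))
        stop("feature axis mismatch between data and PCAModel")
    sweep(x, 2, model@center) %*% model@loadings
}

#' @rdname pcaTransform
#' @param scores samples x components score matrix
#' @return `pcaInverseTransform` returns the reconstruction in feature
#'   space (exact when all components were kept)
#' @export
pcaInverseTransform <- function(scores, model) {
    sweep(as.matrix(scores) %*% t(model@loadings), 2, model@center, "+")
}
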