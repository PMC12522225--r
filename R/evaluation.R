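## Screening-oriented evaluation: ROC/AUC with DeLong variance, paired
## DeLong comparison, Youden thresholds, Wald proportion CIs, subgroup
## sensitivity reports, and baseline-comparability statistics.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random case scores above a random control, with
#' ties counted one half -- computed from ranks, so it equals exhaustive
#' pair counting exactly.
#'
#' @param scores numeric risk scores (higher = more case-like)
#' @param labels case/control labels (see [ttestDifferential()] for
#'   accepted encodings)
#' @return AUC in \[0, 1\]
#' @examples
#' aucScore(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)) # 0.75
#' @export
aucScore <- function(scores, labels) {
    case <- isCase(labels)
    n1 <- sum(case); n0 <- sum(!case)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(scores)           # midranks handle ties as 1/2
    (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve over all candidate thresholds
#'
#' Sensitivity and specificity at every distinct score cut (positive call
#' iff score >= threshold), with sentinel endpoints (sens 1 / spec 0 and
#' sens 0 / spec 1).
#'
#' @inheritParams aucScore
#' @return data.frame with columns threshold, sensitivity, specificity,
#'   ordered by rising threshold
#' @export
rocCurve <- function(scores, labels) {
    case <- isCase(labels)
    if (!any(case) || all(case)) stop("both classes must be present")
    thr <- c(-Inf, sort(unique(scores)), Inf)
    sens <- vapply(thr, function(t) mean(scores[case] >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(scores[!case] < t), numeric(1))
    data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Trapezoidal area under a ROC curve
#' @param roc output of [rocCurve()]
#' @return AUC computed by trapezoidal integration in (1 - spec, sens)
#'   space; equals [aucScore()] up to float tolerance
#' @export
rocAuc <- function(roc) {
    fpr <- rev(1 - roc$specificity)
    tpr <- rev(roc$sensitivity)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## DeLong structural components (placements): for each case, the fraction
## of controls it beats (ties 1/2), and symmetrically for controls.
delongPlacements <- function(scores, case) {
    x <- scores[case]; y <- scores[!case]
    m <- length(x); n <- length(y)
    r <- rank(c(x, y))
    rx <- rank(x); ry <- rank(y)
    v10 <- (r[seq_len(m)] - rx) / n              # per-case placements
    v01 <- 1 - (r[m + seq_len(n)] - ry) / m      # per-control placements
    list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance and confidence interval
#'
#' Nonparametric variance of the AUC from DeLong structural components
#' (per-case and per-control placement values), with a normal-
#' approximation CI clipped to \[0, 1\].  A zero variance with the AUC
#' strictly inside (0, 1) is degenerate and flagged.
#'
#' @inheritParams aucScore
#' @param level confidence level (default 0.95)
#' @return list with auc, variance, ci (length-2), level, degenerate flag
#' @export
delongCi <- function(scores, labels, level = 0.95) {
    case <- isCase(labels)
    if (sum(case) < 2L || sum(!case) < 2L)
        stop("need at least 2 samples per class")
    pl <- delongPlacements(scores, case)
    v <- var(pl$v10) / pl$m + var(pl$v01) / pl$n
    z <- qnorm(1 - (1 - level) / 2)
    ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(v)))
    list(auc = pl$auc, variance = v, ci = ci, level = level,
         degenerate = v == 0 && pl$auc > 0 && pl$auc < 1)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares two models scored on the same samples.  The variance of the
#' AUC difference uses the covariance of the shared structural components;
#' z = (AUC_A - AUC_B) / se and the p-value is two-sided normal.  When the
#' variance of the difference is zero the comparison is degenerate: p is
#' reported as 1 when the AUCs are identical, otherwise an error is
#' raised.
#'
#' @param scoresA,scoresB score vectors over the same samples (paired)
#' @inheritParams aucScore
#' @return list with aucA, aucB, delta, z, p
#' @export
delongPairedTest <- function(scoresA, scoresB, labels) {
    if (length(scoresA) != length(scoresB))
        stop("unpaired inputs: score vectors differ in length")
    case <- isCase(labels)
    if (length(case) != length(scoresA))
        stop("labels must cover all samples")
    a <- delongPlacements(scoresA, case)
    b <- delongPlacements(scoresB, case)
    s10 <- stats::cov(cbind(a$v10, b$v10))
    s01 <- stats::cov(cbind(a$v01, b$v01))
    vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
    delta <- a$auc - b$auc
    if (vd <= 0) {
        if (abs(delta) < 1e-12)
            return(list(aucA = a$auc, aucB = b$auc, delta = 0, z = 0,
                        p = 1))
        stop("degenerate DeLong comparison: zero variance with nonzero ",
             "AUC difference")
    }
    z <- delta / sqrt(vd)
    list(aucA = a$auc, aucB = b$auc, delta = delta, z = z,
         p = 2 * pnorm(-abs(z)))
}

#' Youden-index optimal threshold
#'
#' Maximises J = sensitivity + specificity - 1 over candidate cut-points:
#' the midpoints between adjacent distinct sorted scores plus -Inf/Inf
#' sentinels (positive call iff score >= threshold).  Ties in J are broken
#' toward higher sensitivity -- a screening context prefers not to miss
#' cases -- then toward the lower threshold.
#'
#' @inheritParams aucScore
#' @return list with threshold, J, sensitivity, specificity
#' @export
youdenThreshold <- function(scores, labels) {
    case <- isCase(labels)
    if (!any(case) || all(case)) stop("both classes must be present")
    u <- sort(unique(scores))
    cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
    sens <- vapply(cand, function(t) mean(scores[case] >= t), numeric(1))
    spec <- vapply(cand, function(t) mean(scores[!case] < t), numeric(1))
    J <- sens + spec - 1
    best <- order(-J, -sens, cand)[1]
    list(threshold = cand[best], J = J[best], sensitivity = sens[best],
         specificity = spec[best])
}

#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval `p +- z * sqrt(p(1-p)/n)` on the
#' percentage scale, clipped to \[0, 100\]; Wilson score interval
#' available by flag.
#'
#' @param k successes
#' @param n trials
#' @param level confidence level (default 0.95)
#' @param method `"wald"` (default) or `"wilson"`
#' @return named vector: estimate, lower, upper (percent)
#' @export
proportionCi <- function(k, n, level = 0.95, method = c("wald", "wilson")) {
    method <- match.arg(method)
    z <- qnorm(1 - (1 - level) / 2)
    p <- k / n
    if (method == "wald") {
        half <- z * sqrt(p * (1 - p) / n)
        lo <- p - half; hi <- p + half
    } else {
        den <- 1 + z^2 / n
        ctr <- (p + z^2 / (2 * n)) / den
        half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
        lo <- ctr - half; hi <- ctr + half
    }
    c(estimate = 100 * p, lower = max(0, 100 * lo),
      upper = min(100, 100 * hi))
}

#' Screening metrics at a fixed threshold
#'
#' Calls a sample positive iff its score >= `threshold`, then reports
#' overall sensitivity (over ESPL and ESCC samples), specificity (over
#' controls), per-case-subgroup sensitivities -- each with a 95% Wald CI
#' clipped to \[0, 100\]% -- and the confusion matrix.  Empty subgroups are
#' omitted with a note rather than reported as NaN.
#'
#' @param scores numeric risk scores
#' @param meta cohort metadata covering all scored samples (columns
#'   `group`, `subgroup`)
#' @param threshold finite decision threshold
#' @param level CI level (default 0.95)
#' @param ciMethod `"wald"` (default) or `"wilson"`
#' @return list of class `ScreeningReport`: overall (data.frame),
#'   subgroups (data.frame), confusion (2x2 table), threshold, notes
#' @export
screeningMetrics <- function(scores, meta, threshold, level = 0.95,
                             ciMethod = "wald") {
    stopifnot(is.finite(threshold), nrow(meta) == length(scores))
    case <- meta$group != "control"
    pos <- scores >= threshold
    row1 <- function(what, k, n) {
        ci <- proportionCi(k, n, level, ciMethod)
        data.frame(metric = what, k = k, n = n,
                   estimate = ci["estimate"], lower = ci["lower"],
                   upper = ci["upper"], row.names = NULL)
    }
    overall <- rbind(
        row1("sensitivity", sum(pos & case), sum(case)),
        row1("specificity", sum(!pos & !case), sum(!case)))
    caseSubs <- intersect(subgroupLevels(),
                          c("LGIN", "HGIN", "StageI", "StageII",
                            "StageIII", "StageIV"))
    notes <- character(0)
    subRows <- list()
    for (sg in caseSubs) {
        i <- meta$subgroup == sg
        if (!any(i)) {
            notes <- c(notes, paste0("subgroup ", sg,
                                     " empty; sensitivity omitted"))
            next
        }
        subRows[[sg]] <- row1(sg, sum(pos & i), sum(i))
    }
    confusion <- table(
        truth = factor(ifelse(case, "case", "control"),
                       levels = c("case", "control")),
        call = factor(ifelse(pos, "positive", "negative"),
                      levels = c("positive", "negative")))
    structure(list(overall = overall,
                   subgroups = do.call(rbind, subRows),
                   confusion = confusion, threshold = threshold,
                   notes = notes),
              class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
    cat("ScreeningReport at threshold", sprintf("%.3f", x$threshold), "\n")
    ov <- x$overall
    for (i in seq_len(nrow(ov)))
        cat(sprintf("  %s: %.1f%% (%.1f-%.1f), %d/%d\n", ov$metric[i],
                    ov$estimate[i], ov$lower[i], ov$upper[i], ov$k[i],
                    ov$n[i]))
    if (!is.null(x$subgroups))
        for (i in seq_len(nrow(x$subgroups)))
            cat(sprintf("  %s sensitivity: %.1f%% (%d/%d)\n",
                        x$subgroups$metric[i], x$subgroups$estimate[i],
                        x$subgroups$k[i], x$subgroups$n[i]))
    invisible(x)
}

#' Single-marker threshold classifier
#'
#' Evaluates one protein marker as a standalone screening rule: positive
#' iff the value >= threshold (or <= for `low_is_positive`), fed through
#' the same screening-report machinery as the models.  The marker's AUC is
#' the plain [aucScore()] on raw values (sign-flipped for
#' `low_is_positive`); samples with missing values are excluded and
#' counted.
#'
#' @param values marker measurements
#' @param meta cohort metadata (`group`, `subgroup`)
#' @param threshold decision threshold on the marker scale
#' @param direction `"high_is_positive"` (default) or `"low_is_positive"`
#' @return list: calls (logical), report ([screeningMetrics()]), auc,
#'   nMissing
#' @export
markerThresholdClassifier <- function(values, meta, threshold,
                                      direction = c("high_is_positive",
                                                    "low_is_positive")) {
    direction <- match.arg(direction)
    ok <- !is.na(values)
    v <- values[ok]
    m <- meta[ok, , drop = FALSE]
    sc <- if (direction == "high_is_positive") v else -v
    thr <- if (direction == "high_is_positive") threshold else -threshold
    report <- screeningMetrics(sc, m, thr)
    list(calls = sc >= thr, report = report,
         auc = aucScore(sc, m$group != "control"),
         nMissing = sum(!ok))
}

#' Pearson chi-square test of independence
#'
#' Thin wrapper over [stats::chisq.test()]: Pearson's statistic with
#' expected counts from the margins; the Yates continuity correction is
#' applied only when requested and only for 2x2 tables (larger tables are
#' never corrected).
#'
#' @param counts non-negative integer contingency matrix (>= 2 rows and
#'   columns)
#' @param correction apply the continuity correction (2x2 only)
#' @return list with statistic, df, p
#' @export
chisqIndependence <- function(counts, correction = FALSE) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2L || ncol(counts) < 2L)
        stop("need at least a 2x2 table")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        stop("zero row or column margin")
    corr <- correction && nrow(counts) == 2L && ncol(counts) == 2L
    ht <- suppressWarnings(chisq.test(counts, correct = corr))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H,
#' chi-square approximation with k - 1 df).  When every value is
#' identical across all groups the statistic is 0 with p = 1.
#'
#' @param values numeric measurements
#' @param groups group labels (>= 2 non-empty groups)
#' @return list with statistic, df, p
#' @export
kruskalWallis <- function(values, groups) {
    groups <- factor(groups)
    groups <- droplevels(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
    if (length(unique(values)) == 1L)
        return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1))
    ht <- kruskal.test(values, groups)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}
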