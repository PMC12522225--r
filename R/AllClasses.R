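#' @import methods
#' @importFrom stats rgamma rnbinom rmultinom rnorm rlnorm rbinom runif
#'   sd var qnorm pnorm pchisq pt chisq.test kruskal.test median quantile
#'   setNames predict p.adjust cov
#' @importFrom utils head tail write.table read.delim
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Central container: 256 motifs x n samples, Bioconductor orientation
## (features in rows, samples in columns).  Assays: "counts" always,
## "ratio" and "zscore" added by countsToRatios()/applyZscore().

#' MotifExperiment: container for cfDNA end-motif profiles
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding
#' per-sample terminal 4-mer end-motif profiles.  Rows are the \eqn{4^k}
#' motifs in lexicographic order (k = 4 throughout the pipeline, giving 256
#' rows named \code{AAAA} ... \code{TTTT}); columns are samples.  The
#' \code{"counts"} assay holds non-negative integer end counts; derived
#' assays \code{"ratio"} (count relative to the per-sample mean over all
#' motifs) and \code{"zscore"} are attached by [countsToRatios()] and
#' [applyZscore()].  Per-sample bookkeeping (\code{usable_fragments},
#' group/subgroup metadata, split assignment) lives in \code{colData};
#' planted ground truth from the synthetic generator lives in
#' \code{metadata(x)$planted}.
#'
#' @seealso [MotifExperiment()], [motifCounts()], [countsToRatios()]
#' @exportClass MotifExperiment
setClass("MotifExperiment", contains = "SummarizedExperiment")

setValidity("MotifExperiment", function(object) {
    msg <- NULL
    k <- round(log(nrow(object), 4))
    if (4^k != nrow(object))
        msg <- c(msg, "number of rows must be a power of 4")
    else if (!identical(rownames(object), enumerateMotifs(k)))
        msg <- c(msg, "rownames must be the lexicographically ordered motifs")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MotifExperiment from an end-motif count matrix
#'
#' @param counts numeric matrix of end-motif counts.  Either motifs x
#'   samples (rownames are the 4-mers) or samples x motifs (colnames are the
#'   4-mers); the samples-in-rows orientation is transposed on the way in.
#' @param colData optional `DataFrame`/`data.frame` of per-sample metadata
#'   (one row per sample).
#' @param planted optional list with integer or character vectors `up` and
#'   `down` naming the motifs carrying a planted effect (synthetic data
#'   ground truth); stored in `metadata()`.
#' @return A [MotifExperiment-class] with a `counts` assay and a
#'   `usable_fragments` column (per-sample total count) in `colData`.
#' @examples
#' m <- matrix(rpois(256 * 4, 40), nrow = 256,
#'             dimnames = list(enumerateMotifs(4), paste0("s", 1:4)))
#' me <- MotifExperiment(m)
#' @export
MotifExperiment <- function(counts, colData = NULL, planted = NULL) {
    counts <- as.matrix(counts)
    motifs <- enumerateMotifs(round(log(max(dim(counts)), 4)))
    if (!is.null(colnames(counts)) && all(motifs %in% colnames(counts)))
        counts <- t(counts[, motifs, drop = FALSE])
    if (is.null(rownames(counts)) && nrow(counts) == length(motifs))
        rownames(counts) <- motifs
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(counts))
    else {
        colData <- S4Vectors::DataFrame(colData)
        rownames(colData) <- colnames(counts)
    }
    colData$usable_fragments <- colSums(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = colData)
    if (!is.null(planted))
        S4Vectors::metadata(se)$planted <- planted
    new("MotifExperiment", se)
}

#' @describeIn MotifExperiment end-motif count matrix (motifs x samples)
#' @param x a `MotifExperiment`
#' @export
motifCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn MotifExperiment ratio-to-average matrix; error if
#'   [countsToRatios()] has not been run
#' @export
motifRatios <- function(x) {
    if (!"ratio" %in% SummarizedExperiment::assayNames(x))
        stop("no 'ratio' assay; run countsToRatios() first")
    SummarizedExperiment::assay(x, "ratio")
}

#' @describeIn MotifExperiment Z-score matrix; error if [applyZscore()] has
#'   not been run
#' @export
motifZ <- function(x) {
    if (!"zscore" %in% SummarizedExperiment::assayNames(x))
        stop("no 'zscore' assay; run applyZscore() first")
    SummarizedExperiment::assay(x, "zscore")
}

#' @describeIn MotifExperiment per-sample usable fragment totals
#' @export
usableFragments <- function(x) x$usable_fragments

#' @describeIn MotifExperiment planted up/down motif ground truth (synthetic
#'   cohorts), or NULL
#' @export
plantedMotifs <- function(x) S4Vectors::metadata(x)$planted

setMethod("show", "MotifExperiment", function(object) {
    cat("MotifExperiment:", nrow(object), "motifs x", ncol(object),
        "samples\n")
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
    uf <- usableFragments(object)
    if (length(uf))
        cat("  usable fragments/sample: median",
            format(median(uf), big.mark = ","), "\n")
    pl <- plantedMotifs(object)
    if (!is.null(pl))
        cat("  planted effects:", length(pl$up), "up,",
            length(pl$down), "down\n")
})

#' Simulation configuration for synthetic screening cohorts
#'
#' Holds every knob of the synthetic cohort generator: subgroup sizes, the
#' planted motif effect (number of up/down motifs, log-scale effect size,
#' per-subgroup severity multipliers), the Dirichlet concentration governing
#' between-sample motif variability, the negative-binomial fragment-total
#' model, and per-marker log-normal protein parameters with group-level
#' shifts.  Construct with [simulationConfig()], which supplies defaults.
#'
#' @slot nPerSubgroup named integer vector of samples per subgroup
#' @slot nUpMotifs,nDownMotifs number of planted up/down-regulated motifs
#' @slot effectDelta log-scale shift applied to planted motif probabilities
#' @slot severityScaling named multiplier in \[0, 1\] per subgroup,
#'   non-decreasing along LGIN, HGIN, StageI..StageIV
#' @slot dirichletConcentration Dirichlet concentration (larger = less
#'   between-sample variability)
#' @slot fragmentsMean,fragmentsDispersion negative-binomial mean and size
#'   for per-sample fragment totals
#' @slot proteinParams data.frame with columns marker, meanlog, sdlog,
#'   shift_ESPL, shift_ESCC (multiplicative group shifts)
#' @slot seed integer random seed
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
    nPerSubgroup = "integer",
    nUpMotifs = "integer",
    nDownMotifs = "integer",
    effectDelta = "numeric",
    severityScaling = "numeric",
    dirichletConcentration = "numeric",
    fragmentsMean = "numeric",
    fragmentsDispersion = "numeric",
    proteinParams = "data.frame",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@nUpMotifs + object@nDownMotifs > 256L)
        msg <- c(msg, "nUpMotifs + nDownMotifs must be <= 256")
    if (any(object@nPerSubgroup < 0L))
        msg <- c(msg, "subgroup counts must be non-negative")
    if (!all(names(object@nPerSubgroup) %in% subgroupLevels()))
        msg <- c(msg, "unknown subgroup name in nPerSubgroup")
    if (sum(object@nPerSubgroup) == 0L)
        msg <- c(msg, "cohort is empty: all subgroup counts are zero")
    if (object@dirichletConcentration <= 0)
        msg <- c(msg, "dirichletConcentration must be > 0")
    if (object@fragmentsMean <= 0 || object@fragmentsDispersion <= 0)
        msg <- c(msg, "fragment total parameters must be > 0")
    if (!is.finite(object@effectDelta))
        msg <- c(msg, "effectDelta must be finite")
    sev <- object@severityScaling
    ord <- c("LGIN", "HGIN", "StageI", "StageII", "StageIII", "StageIV")
    if (!all(ord %in% names(sev)))
        msg <- c(msg, "severityScaling must cover LGIN..StageIV")
    else if (any(diff(sev[ord]) < -1e-12))
        msg <- c(msg, "severityScaling must be non-decreasing from LGIN to StageIV")
    if (any(sev < 0 | sev > 1))
        msg <- c(msg, "severityScaling entries must lie in [0, 1]")
    pp <- object@proteinParams
    need <- c("marker", "meanlog", "sdlog", "shift_ESPL", "shift_ESCC")
    if (!all(need %in% names(pp)))
        msg <- c(msg, "proteinParams must have columns marker, meanlog, sdlog, shift_ESPL, shift_ESCC")
    else {
        if (!setequal(pp$marker, proteinMarkers()))
            msg <- c(msg, "proteinParams must cover the nine measured markers")
        if (any(pp$sdlog <= 0) || any(pp$shift_ESPL <= 0) ||
            any(pp$shift_ESCC <= 0))
            msg <- c(msg, "protein scale and shift parameters must be > 0")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", sum(object@nPerSubgroup), "samples (",
        paste(names(object@nPerSubgroup), object@nPerSubgroup,
              sep = "=", collapse = ", "), ")\n")
    cat("  planted motifs:", object@nUpMotifs, "up /", object@nDownMotifs,
        "down, effect delta", object@effectDelta, "\n")
    cat("  fragments/sample: NB(mean", object@fragmentsMean, ", size",
        object@fragmentsDispersion, "); Dirichlet conc.",
        object@dirichletConcentration, "\n")
    cat("  seed:", object@seed, "\n")
})

#' Per-motif standardisation statistics
#'
#' Mean and sample standard deviation of each motif's ratio value over a
#' designated fitting set (normally the training split), as fitted by
#' [fitZscore()] and consumed by [applyZscore()].  Motifs with zero
#' variance on the fitting set are listed in `constant` and mapped to
#' Z = 0 on application so the 256-column geometry stays fixed.
#'
#' @slot mean,sd named per-motif statistics (n - 1 denominator for sd)
#' @slot constant character vector of zero-variance motifs
#' @slot nFit number of fitting samples
#' @exportClass ScalerStats
setClass("ScalerStats", representation(
    mean = "numeric", sd = "numeric", constant = "character",
    nFit = "integer"))

setValidity("ScalerStats", function(object) {
    msg <- NULL
    if (!identical(names(object@mean), names(object@sd)))
        msg <- c(msg, "mean and sd must share the motif axis")
    if (any(object@sd < 0)) msg <- c(msg, "sd must be >= 0")
    if (object@nFit < 2L) msg <- c(msg, "fitting-set size must be >= 2")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ScalerStats", function(object) {
    cat("ScalerStats over", length(object@mean), "motifs, fitted on",
        object@nFit, "samples;", length(object@constant),
        "constant motif(s)\n")
})

#' Differential feature-selection result
#'
#' Per-feature two-sample t statistics comparing cases (ESCC and
#' precancerous lesions pooled) with controls, the two-sided p-value, the
#' case-minus-control mean difference and its direction, and the selection
#' mask at the recorded alpha (no multiplicity correction by default).
#' Produced by [ttestDifferential()].
#'
#' @slot table data.frame with columns feature, t, p, meanDiff, direction,
#'   selected, flag
#' @slot alpha selection threshold on the raw two-sided p-value
#' @slot variance `"equal"` (pooled, Student) or `"unequal"` (Welch)
#' @exportClass DifferentialResult
setClass("DifferentialResult", representation(
    table = "data.frame", alpha = "numeric", variance = "character"))

setMethod("show", "DifferentialResult", function(object) {
    tab <- object@table
    cat("DifferentialResult:", sum(tab$selected), "of", nrow(tab),
        "features selected at p <", object@alpha,
        sprintf("(%d up, %d down)\n",
                sum(tab$selected & tab$direction == "up"),
                sum(tab$selected & tab$direction == "down")))
})

#' @describeIn DifferentialResult selected feature names
#' @param x a `DifferentialResult`
#' @export
selectedFeatures <- function(x) x@table$feature[x@table$selected]

#' @describeIn DifferentialResult the full per-feature table
#' @export
differentialTable <- function(x) x@table

#' Principal component model fitted on the training split
#'
#' Training means and orthonormal loading vectors of the selected-motif
#' submatrix, with explained-variance fractions.  Each component's sign is
#' fixed so its largest-magnitude loading is positive, making the fit
#' deterministic.  Produced by [pcaFit()], applied by [pcaTransform()].
#'
#' @slot center named training means per input feature
#' @slot loadings feature x component matrix of orthonormal loadings
#' @slot eigenvalues per-component variances (training covariance
#'   eigenvalues)
#' @slot varianceExplained fractions of total variance, non-increasing
#' @exportClass PCAModel
setClass("PCAModel", representation(
    center = "numeric", loadings = "matrix", eigenvalues = "numeric",
    varianceExplained = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- NULL
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
        msg <- c(msg, "loading vectors must be orthonormal")
    ve <- object@varianceExplained
    if (any(diff(ve) > 1e-12) || sum(ve) > 1 + 1e-9)
        msg <- c(msg, "explained-variance fractions must be non-increasing and sum to <= 1")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", ncol(object@loadings), "components over",
        nrow(object@loadings), "features;",
        sprintf("%.1f%% variance explained\n",
                100 * sum(object@varianceExplained)))
})

#' Recursive feature elimination result
#'
#' Elimination-order ranking from random-forest RF-RFE (rank 1 = retained
#' longest), the mean cross-validated AUC at every candidate subset size,
#' and the chosen subset (the size maximising mean CV AUC, ties broken
#' toward the smaller subset).  Produced by [rfeSelect()].
#'
#' @slot ranking character vector, a permutation of the input features in
#'   rank order (best first)
#' @slot cvTrace data.frame with columns size, meanAUC
#' @slot chosen character vector of chosen feature names
#' @slot metric scoring metric name (`"auc"`)
#' @slot folds integer fold assignment used for every subset size
#' @slot seed integer seed
#' @exportClass RFEResult
setClass("RFEResult", representation(
    ranking = "character", cvTrace = "data.frame", chosen = "character",
    metric = "character", folds = "integer", seed = "integer"))

setMethod("show", "RFEResult", function(object) {
    best <- object@cvTrace[object@cvTrace$size == length(object@chosen), ]
    cat("RFEResult:", length(object@chosen), "of", length(object@ranking),
        "features chosen (mean CV", object@metric, "=",
        sprintf("%.3f", best$meanAUC[1]), ")\n")
})

#' Fitted screening model (motif, protein or combined recipe)
#'
#' Bundles the frozen upstream state needed to score raw validation/test
#' samples with no refitting: the Z-score scaler, the differential motif
#' selection and PCA model (motif and combined recipes), the RF-RFE chosen
#' feature list, and the final ranger random forest with its fold-level CV
#' bookkeeping.  Produced by [buildRecipe()] or [fitRandomForest()]; scored
#' with [predictScores()].
#'
#' @slot recipe one of `"motif"`, `"protein"`, `"combined"`
#' @slot scaler [ScalerStats-class] or NULL (protein recipe)
#' @slot differential [DifferentialResult-class] or NULL
#' @slot pca [PCAModel-class] or NULL
#' @slot rfe [RFEResult-class] or NULL
#' @slot features character vector of model feature names
#' @slot forest the fitted `ranger` object
#' @slot hyper chosen hyperparameters (named list)
#' @slot cvScores per-fold CV AUCs of the chosen hyperparameter point
#' @slot importance named, non-negative, sums to 1
#' @slot seed integer seed
#' @exportClass ScreenModel
setClass("ScreenModel", representation(
    recipe = "character", scaler = "ANY", differential = "ANY",
    pca = "ANY", rfe = "ANY", features = "character", forest = "ANY",
    hyper = "list", cvScores = "numeric", importance = "numeric",
    seed = "integer"))

setValidity("ScreenModel", function(object) {
    msg <- NULL
    if (!object@recipe %in% c("motif", "protein", "combined"))
        msg <- c(msg, "recipe must be motif, protein or combined")
    imp <- object@importance
    if (length(imp) && (any(imp < -1e-12) || abs(sum(imp) - 1) > 1e-6))
        msg <- c(msg, "importances must be non-negative and sum to 1")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ScreenModel", function(object) {
    cat("ScreenModel (", object@recipe, " recipe): ",
        length(object@features), " features, ",
        object@hyper$num.trees, " trees\n", sep = "")
    cat("  mean CV AUC:", sprintf("%.3f", mean(object@cvScores)), "over",
        length(object@cvScores), "folds\n")
    top <- head(sort(object@importance, decreasing = TRUE), 5)
    cat("  top features:", paste(names(top), collapse = ", "), "\n")
})

#' @describeIn ScreenModel model feature names
#' @param x a `ScreenModel`
#' @export
modelFeatures <- function(x) x@features

#' @describeIn ScreenModel normalised feature importances
#' @export
featureImportance <- function(x) x@importance
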