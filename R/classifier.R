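## Random-forest recursive feature elimination and model fitting.  The
## forest engine is ranger (probability forests, impurity importance),
## run single-threaded with an explicit seed so every fit is
## deterministic.

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `nFolds` folds, stratifying by class so
#' every fold contains both classes whenever the class sizes permit.
#'
#' @param case logical class indicator
#' @param nFolds number of folds (>= 2)
#' @param seed integer seed
#' @return integer fold assignment in 1..nFolds
#' @export
stratifiedFolds <- function(case, nFolds = 10L, seed = 1L) {
    if (nFolds < 2L) stop("nFolds must be >= 2")
    folds <- integer(length(case))
    withSeed(seed, {
        for (cl in unique(case)) {
            i <- which(case == cl)
            folds[i] <- sample(rep_len(seq_len(nFolds), length(i)))
        }
    })
    folds
}

## one deterministic ranger fit
.fitForest <- function(x, y, numTrees, seed, importance = "none") {
    ranger::ranger(x = x, y = y, num.trees = numTrees,
                   probability = TRUE, importance = importance,
                   seed = seed, num.threads = 1,
                   respect.unordered.factors = "order")
}

.forestScores <- function(fit, x)
    predict(fit, data = x, num.threads = 1, seed = 1L)$predictions[, "case"]

## mean CV AUC of a feature subset under fixed folds
.cvAuc <- function(x, y, folds, numTrees, seed) {
    aucs <- vapply(sort(unique(folds)), function(f) {
        fit <- .fitForest(x[folds != f, , drop = FALSE], y[folds != f],
                          numTrees, seed + f)
        sc <- .forestScores(fit, x[folds == f, , drop = FALSE])
        aucScore(sc, y[folds == f] == "case")
    }, numeric(1))
    mean(aucs)
}

.asLabelFactor <- function(labels)
    factor(ifelse(isCase(labels), "case", "control"),
           levels = c("control", "case"))

#' Recursive feature elimination with random forests (RF-RFE)
#'
#' Starting from the full feature set, repeatedly: score the current
#' subset by mean AUC over shared stratified cross-validation folds, fit a
#' forest on all training samples, and drop the `step` features with the
#' lowest impurity importance.  The returned ranking is the elimination
#' order reversed (rank 1 = survived longest); the chosen subset is the
#' candidate size with the highest mean CV AUC, ties broken toward the
#' smaller subset.
#'
#' @param x samples x features data.frame or matrix
#' @param labels case/control labels
#' @param nFolds folds for the shared CV (default 10, stratified)
#' @param step features removed per iteration (default 1)
#' @param numTrees trees per forest (default 250; the final model refit
#'   uses its own hyperparameters)
#' @param seed integer seed (folds and forests)
#' @return an [RFEResult-class]
#' @export
rfeSelect <- function(x, labels, nFolds = 10L, step = 1L, numTrees = 250L,
                      seed = 1L) {
    x <- as.data.frame(x)
    ## canonical column order: the ranking is exactly invariant to the
    ## caller's feature column permutation
    x <- x[, sort(colnames(x)), drop = FALSE]
    y <- .asLabelFactor(labels)
    if (nlevels(droplevels(y)) < 2L) stop("labels contain a single class")
    folds <- stratifiedFolds(y == "case", nFolds, deriveSeed(seed, "folds"))
    current <- colnames(x)
    eliminated <- character(0)
    trace <- list()
    it <- 0L
    while (length(current) >= 1L) {
        it <- it + 1L
        sub <- x[, current, drop = FALSE]
        trace[[it]] <- data.frame(
            size = length(current),
            meanAUC = .cvAuc(sub, y, folds, numTrees,
                             deriveSeed(seed, paste0("cv", it))))
        if (length(current) == 1L) break
        fit <- .fitForest(sub, y, numTrees,
                          deriveSeed(seed, paste0("imp", it)),
                          importance = "impurity")
        imp <- fit$variable.importance
        drop <- names(sort(imp))[seq_len(min(step, length(current) - 1L))]
        eliminated <- c(eliminated, drop)
        current <- setdiff(current, drop)
    }
    ranking <- c(current, rev(eliminated))
    cvTrace <- do.call(rbind, trace)
    best <- cvTrace$size[order(-cvTrace$meanAUC, cvTrace$size)][1]
    new("RFEResult", ranking = ranking, cvTrace = cvTrace,
        chosen = ranking[seq_len(best)], metric = "auc",
        folds = folds, seed = as.integer(seed))
}

#' Fit a random-forest screening model with cross-validated tuning
#'
#' Scores every hyperparameter grid point by mean AUC over stratified
#' 10-fold cross-validation, refits the best point on the full training
#' split, and freezes the fold-level CV scores and normalised feature
#' importances.  Deterministic under the seed.
#'
#' @param x training samples x features (data.frame or matrix)
#' @param labels case/control labels
#' @param hyperGrid data.frame of candidate hyperparameters (column
#'   `num.trees`; default a single 500-tree point)
#' @param nFolds CV folds (default 10)
#' @param seed integer seed
#' @param recipe recipe tag stored on the model
#' @return a [ScreenModel-class] (upstream slots empty; see
#'   [buildRecipe()] for the full pipelines)
#' @export
fitRandomForest <- function(x, labels,
                            hyperGrid = data.frame(num.trees = 500L),
                            nFolds = 10L, seed = 1L, recipe = "protein") {
    x <- as.data.frame(x)
    y <- .asLabelFactor(labels)
    if (nlevels(droplevels(y)) < 2L) stop("labels contain a single class")
    if (nrow(hyperGrid) < 1L) stop("empty hyperparameter grid")
    folds <- stratifiedFolds(y == "case", nFolds,
                             deriveSeed(seed, "tunefolds"))
    gridScores <- vapply(seq_len(nrow(hyperGrid)), function(g) {
        .cvAuc(x, y, folds, hyperGrid$num.trees[g],
               deriveSeed(seed, paste0("grid", g)))
    }, numeric(1))
    best <- which.max(gridScores)
    perFold <- vapply(sort(unique(folds)), function(f) {
        fit <- .fitForest(x[folds != f, , drop = FALSE], y[folds != f],
                          hyperGrid$num.trees[best],
                          deriveSeed(seed, paste0("grid", best)) + f)
        aucScore(.forestScores(fit, x[folds == f, , drop = FALSE]),
                 y[folds == f] == "case")
    }, numeric(1))
    forest <- .fitForest(x, y, hyperGrid$num.trees[best],
                         deriveSeed(seed, "final"),
                         importance = "impurity")
    imp <- forest$variable.importance
    imp <- pmax(imp, 0)
    imp <- if (sum(imp) > 0) imp / sum(imp) else
        setNames(rep(1 / length(imp), length(imp)), names(imp))
    new("ScreenModel", recipe = recipe, scaler = NULL,
        differential = NULL, pca = NULL, rfe = NULL,
        features = colnames(x), forest = forest,
        hyper = list(num.trees = hyperGrid$num.trees[best],
                     mtry = forest$mtry),
        cvScores = perFold, importance = imp, seed = as.integer(seed))
}

#' Assemble model features from raw inputs using frozen state
#'
#' Applies the model's frozen upstream transforms -- training-fitted
#' Z-score statistics, differential motif selection and PCA for motif
#' features; the raw ten-marker table for protein features -- to new
#' samples, with no refitting.
#'
#' @param model a [ScreenModel-class]
#' @param motifs a [MotifExperiment-class] with a `ratio` assay (motif and
#'   combined recipes)
#' @param proteins protein table with the ten feature columns (protein and
#'   combined recipes)
#' @return samples x features data.frame on the model's feature axis
#' @export
buildFeatures <- function(model, motifs = NULL, proteins = NULL) {
    parts <- list()
    if (model@recipe %in% c("motif", "combined")) {
        if (is.null(motifs)) stop("motif layer required for the ",
                                  model@recipe, " recipe")
        me <- applyZscore(motifs, model@scaler)
        z <- t(motifZ(me))
        sel <- selectedFeatures(model@differential)
        parts$motif <- as.data.frame(
            pcaTransform(z[, sel, drop = FALSE], model@pca))
    }
    if (model@recipe %in% c("protein", "combined")) {
        if (is.null(proteins)) stop("protein layer required for the ",
                                    model@recipe, " recipe")
        miss <- setdiff(proteinFeatureNames(), colnames(proteins))
        if (length(miss)) stop("missing marker column(s): ",
                               paste(miss, collapse = ", "))
        pr <- proteins[, proteinFeatureNames(), drop = FALSE]
        rownames(pr) <- proteins$sample_id
        parts$protein <- pr
    }
    feat <- do.call(cbind, unname(parts))
    miss <- setdiff(model@features, colnames(feat))
    if (length(miss)) stop("feature axis mismatch: missing ",
                           paste(head(miss, 5), collapse = ", "))
    feat[, model@features, drop = FALSE]
}

#' Score samples with a fitted screening model
#'
#' Per-sample case-class probability (fraction of trees voting case),
#' bounded in \[0, 1\].  Raw inputs are pushed through the frozen pipeline
#' (scaler, differential selection, PCA where applicable) -- no refitting.
#'
#' @param model a [ScreenModel-class]
#' @param features precomputed samples x features table on the model
#'   axis; or leave NULL and supply `motifs` / `proteins`
#' @inheritParams buildFeatures
#' @return named numeric vector of risk scores in \[0, 1\]
#' @export
predictScores <- function(model, features = NULL, motifs = NULL,
                          proteins = NULL) {
    if (is.null(features))
        features <- buildFeatures(model, motifs, proteins)
    if (!identical(colnames(features), model@features))
        stop("feature axis mismatch")
    sc <- .forestScores(model@forest, as.data.frame(features))
    names(sc) <- rownames(features)
    sc
}

#' Build one of the three screening model recipes
#'
#' Fits the full frozen pipeline on the training split only:
#' \describe{
#'   \item{motif}{t-test differential filter on Z-scored motif ratios ->
#'     PCA to `nComponents` -> RF-RFE over the components -> forest.}
#'   \item{protein}{RF-RFE over the ten marker features (nine measured
#'     plus PGR) -> forest.}
#'   \item{combined}{RF-RFE jointly over the motif principal components
#'     and the ten markers -> forest.  The PCA fit is the identical
#'     training fit used by the motif recipe.}
#' }
#' The number of features the RFE keeps is an outcome reported on the
#' model, never forced; the reference analysis arrived at 16 components,
#' 8 proteins, and 20 components + 6 proteins for the three recipes.
#'
#' @param recipe `"motif"`, `"protein"` or `"combined"`
#' @param motifs training-split [MotifExperiment-class] with a `ratio`
#'   assay (scaler and PCA are fitted here)
#' @param proteins training-split protein table (`sample_id` + markers)
#' @param labels training case/control labels
#' @param nComponents PCA dimensions (default 30)
#' @param alpha differential-test threshold (default 0.05)
#' @param nFolds CV folds (default 10)
#' @param hyperGrid forest hyperparameter grid (default 500 trees)
#' @param rfeTrees trees per RFE forest (default 250)
#' @param seed integer seed
#' @return a [ScreenModel-class] with all frozen upstream state attached
#' @export
buildRecipe <- function(recipe = c("motif", "protein", "combined"),
                        motifs = NULL, proteins = NULL, labels,
                        nComponents = 30L, alpha = 0.05, nFolds = 10L,
                        hyperGrid = data.frame(num.trees = 500L),
                        rfeTrees = 250L, seed = 1L) {
    recipe <- match.arg(recipe)
    scaler <- NULL; diffRes <- NULL; pca <- NULL
    parts <- list()
    if (recipe %in% c("motif", "combined")) {
        if (is.null(motifs)) stop("motif recipe requires a motif layer")
        scaler <- fitZscore(motifs)
        me <- applyZscore(motifs, scaler)
        z <- t(motifZ(me))
        diffRes <- ttestDifferential(z, labels, alpha = alpha)
        sel <- selectedFeatures(diffRes)
        if (length(sel) < 2L)
            stop("fewer than 2 differential motifs selected; ",
                 "cannot fit PCA")
        k <- min(nComponents, nrow(z) - 1L, length(sel))
        pca <- pcaFit(z[, sel, drop = FALSE], k)
        parts$motif <- as.data.frame(
            pcaTransform(z[, sel, drop = FALSE], pca))
    }
    if (recipe %in% c("protein", "combined")) {
        if (is.null(proteins)) stop(recipe,
                                    " recipe requires a protein layer")
        pr <- proteins[, proteinFeatureNames(), drop = FALSE]
        rownames(pr) <- proteins$sample_id
        parts$protein <- pr
    }
    feat <- do.call(cbind, unname(parts))
    rfe <- rfeSelect(feat, labels, nFolds = nFolds, numTrees = rfeTrees,
                     seed = deriveSeed(seed, paste0("rfe_", recipe)))
    model <- fitRandomForest(feat[, rfe@chosen, drop = FALSE], labels,
                             hyperGrid = hyperGrid, nFolds = nFolds,
                             seed = deriveSeed(seed,
                                               paste0("fit_", recipe)),
                             recipe = recipe)
    model@scaler <- scaler
    model@differential <- diffRes
    model@pca <- pca
    model@rfe <- rfe
    validObject(model)
    model
}
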