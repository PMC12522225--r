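## End-to-end orchestration: cohort splitting, baseline comparability,
## the three model recipes on the training split, Youden thresholds on
## the validation split, and final screening evaluation on the test
## split.

## quota sizes by cumulative-floor allocation: n_i = floor(n F_i) -
## floor(n F_{i-1}) with F the cumulative fractions.  Reproduces the
## reference cohort's (240, 103, 148) partition of 491 at
## (0.49, 0.21, 0.30).
quotaSizes <- function(n, fractions) {
    stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions > 0),
              all(fractions < 1))
    cf <- cumsum(fractions)
    cf[length(cf)] <- 1
    sizes <- diff(c(0L, floor(n * cf)))
    setNames(as.integer(sizes), names(fractions))
}

#' Assign train / validation / test splits
#'
#' Partitions the cohort disjointly and exhaustively into the three
#' splits.  Sizes come from cumulative-floor quota allocation of
#' `n * fraction`; with stratification (default: by subgroup) the
#' allocation is applied within each stratum, which keeps small synthetic
#' cohorts balanced.  Strata smaller than 3 are pooled into one global
#' draw with a warning.  Deterministic under the seed.
#'
#' @param meta cohort metadata (one row per sample)
#' @param fractions named fractions summing to 1 (defaults 0.49 / 0.21 /
#'   0.30 for train / validation / test)
#' @param seed integer seed
#' @param stratifyBy metadata column to stratify on, or NULL for a simple
#'   random split (default `"subgroup"`)
#' @return `meta` with the `split` factor column filled in
#' @export
splitCohort <- function(meta,
                        fractions = c(train = 0.49, validation = 0.21,
                                      test = 0.30),
                        seed = 1L, stratifyBy = "subgroup") {
    n <- nrow(meta)
    if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0) ||
        any(fractions >= 1))
        stop("split fractions must lie in (0, 1) and sum to 1")
    if (!is.null(stratifyBy) && !stratifyBy %in% names(meta))
        stop("stratification column '", stratifyBy, "' not in metadata")
    splitNames <- names(fractions)
    assign <- character(n)
    withSeed(deriveSeed(seed, "split"), {
        strata <- if (is.null(stratifyBy)) rep("all", n)
                  else as.character(meta[[stratifyBy]])
        small <- names(which(table(strata) < 3L))
        if (length(small) && !is.null(stratifyBy)) {
            warning("strata smaller than 3 assigned by global draw: ",
                    paste(small, collapse = ", "))
            strata[strata %in% small] <- ".pooled"
        }
        for (st in unique(strata)) {
            i <- which(strata == st)
            sizes <- quotaSizes(length(i), fractions)
            assign[sample(i)] <- rep(splitNames, sizes)
        }
    })
    meta$split <- factor(assign, levels = splitNames)
    meta
}

#' Published reference-cohort baseline tables
#'
#' The categorical baseline-characteristics contingency tables (covariate
#' level x train/validation/test) of the 491-sample reference ESCC
#' screening cohort, shipped as plain text with the package.  Used to
#' exercise [chisqIndependence()] against the published statistics.
#'
#' @return named list of integer matrices (sex, smoking, drinking, group,
#'   subgroup), columns train/validation/test
#' @export
referenceBaselineTables <- function() {
    f <- system.file("extdata", "baseline_counts.tsv",
                     package = "cfMotifScreen", mustWork = TRUE)
    df <- read.delim(f, check.names = FALSE)
    lapply(split(df, factor(df$covariate, unique(df$covariate))),
           function(d) {
               m <- as.matrix(d[, c("train", "validation", "test")])
               rownames(m) <- d$level
               m
           })
}

#' Baseline comparability report across splits
#'
#' Table-1-style comparability check: each categorical covariate is
#' cross-tabulated against the split assignment and tested with
#' [chisqIndependence()]; each numeric covariate is summarised as median
#' (IQR) per split and tested with [kruskalWallis()].  Absent covariates
#' are skipped with a note.
#'
#' @param meta cohort metadata with a filled `split` column
#' @param categorical,numeric covariate column names to test
#' @return data.frame with columns covariate, type, statistic, df, p,
#'   summary; attribute `"notes"` lists skipped covariates
#' @export
baselineReport <- function(meta,
                           categorical = c("sex", "smoking", "drinking",
                                           "group", "subgroup"),
                           numeric = "age") {
    stopifnot(!anyNA(meta$split))
    rows <- list(); notes <- character(0)
    for (cv in numeric) {
        if (!cv %in% names(meta)) {
            notes <- c(notes, paste0("covariate ", cv, " absent; skipped"))
            next
        }
        kw <- kruskalWallis(meta[[cv]], meta$split)
        med <- vapply(split(meta[[cv]], meta$split), function(v)
            sprintf("%.0f (%.0f, %.0f)", median(v),
                    quantile(v, 0.25), quantile(v, 0.75)), character(1))
        rows[[cv]] <- data.frame(
            covariate = cv, type = "numeric", statistic = kw$statistic,
            df = kw$df, p = kw$p,
            summary = paste(names(med), med, sep = ": ", collapse = "; "))
    }
    for (cv in categorical) {
        if (!cv %in% names(meta)) {
            notes <- c(notes, paste0("covariate ", cv, " absent; skipped"))
            next
        }
        tab <- table(meta[[cv]], meta$split)
        tab <- tab[rowSums(tab) > 0, , drop = FALSE]
        cs <- chisqIndependence(tab)
        rows[[cv]] <- data.frame(
            covariate = cv, type = "categorical",
            statistic = cs$statistic, df = cs$df, p = cs$p,
            summary = paste(rownames(tab), collapse = "/"))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "notes") <- notes
    out
}

#' Run the full screening pipeline on one cohort
#'
#' Executes the complete analysis: ratio conversion, stratified cohort
#' split, the requested model recipes fitted on the training split,
#' Youden-index thresholds fixed on the validation split, and final
#' evaluation on the test split -- AUC with DeLong CIs, screening reports,
#' paired DeLong comparisons of every model against the combined and
#' protein models, and single-marker threshold classifiers (each marker's
#' threshold chosen by Youden on the validation split).  All randomness
#' derives from one root seed.  Inputs are either a
#' [SimulationConfig-class] (synthetic mode) or precomputed `motifs` /
#' `proteins` / `meta`.
#'
#' @param simConfig optional [SimulationConfig-class]; generates the
#'   cohort when `motifs` is NULL
#' @param motifs a [MotifExperiment-class] of counts (alternative to
#'   `simConfig`)
#' @param proteins protein table (`sample_id` + ten features)
#' @param meta cohort metadata
#' @param recipes model recipes to fit
#' @param fractions split fractions (defaults 0.49 / 0.21 / 0.30)
#' @param seed root seed
#' @param nComponents,alpha,hyperGrid,rfeTrees,nFolds passed to
#'   [buildRecipe()]
#' @param outDir optional directory; when given, reports, thresholds,
#'   CV traces, importances and the run manifest are written as TSV/JSON
#' @return list of class `ScreenRun`: meta (with splits), models,
#'   thresholds, evaluations (per recipe: auc, ci, report), comparisons
#'   (paired DeLong table), markers (Table-2-style single-marker table),
#'   baseline (comparability report), manifest
#' @export
runPipeline <- function(simConfig = NULL, motifs = NULL, proteins = NULL,
                        meta = NULL,
                        recipes = c("motif", "protein", "combined"),
                        fractions = c(train = 0.49, validation = 0.21,
                                      test = 0.30),
                        seed = 1L, nComponents = 30L, alpha = 0.05,
                        hyperGrid = data.frame(num.trees = 500L),
                        rfeTrees = 250L, nFolds = 10L, outDir = NULL) {
    if (is.null(motifs)) {
        if (is.null(simConfig))
            stop("supply either simConfig or motifs/proteins/meta")
        meta <- generateMetadata(simConfig)
        motifs <- generateMotifCounts(meta, simConfig)
        proteins <- generateProteinPanel(meta, simConfig)
    }
    if (is.null(meta)) meta <- as.data.frame(SummarizedExperiment::colData(motifs))
    motifs <- countsToRatios(motifs)
    meta <- splitCohort(meta, fractions, seed = deriveSeed(seed, "cohort"))
    baseline <- baselineReport(meta)
    idx <- split(seq_len(nrow(meta)), meta$split)
    labels <- meta$group != "control"
    prRows <- match(meta$sample_id, proteins$sample_id)
    sub <- function(i) list(
        motifs = motifs[, i],
        proteins = proteins[prRows[i], , drop = FALSE],
        labels = labels[i], meta = meta[i, , drop = FALSE])
    tr <- sub(idx$train); va <- sub(idx$validation); te <- sub(idx$test)

    models <- list(); thresholds <- list(); evals <- list()
    scoresTest <- list(); scoresVal <- list()
    for (rc in recipes) {
        mod <- buildRecipe(rc, motifs = tr$motifs, proteins = tr$proteins,
                           labels = tr$labels, nComponents = nComponents,
                           alpha = alpha, hyperGrid = hyperGrid,
                           rfeTrees = rfeTrees, nFolds = nFolds,
                           seed = deriveSeed(seed, paste0("model_", rc)))
        scVal <- predictScores(mod, motifs = va$motifs,
                               proteins = va$proteins)
        thr <- youdenThreshold(scVal, va$labels)
        ## infinite sentinels (degenerate optima) mapped to finite cuts
        ## producing the same calls: score >= threshold
        if (thr$threshold == -Inf) thr$threshold <- min(scVal)
        if (thr$threshold == Inf) thr$threshold <- max(scVal) + 1
        scTest <- predictScores(mod, motifs = te$motifs,
                                proteins = te$proteins)
        models[[rc]] <- mod
        thresholds[[rc]] <- thr
        scoresTest[[rc]] <- scTest
        scoresVal[[rc]] <- scVal
        evals[[rc]] <- list(
            auc = delongCi(scTest, te$labels),
            report = screeningMetrics(scTest, te$meta, thr$threshold))
    }

    ## paired DeLong comparisons on the test split (vs combined, vs protein)
    comparisons <- NULL
    compRows <- list()
    refNames <- intersect(c("combined", "protein"), names(scoresTest))
    for (rc in names(scoresTest)) {
        for (ref in refNames) {
            dl <- delongPairedTest(scoresTest[[rc]], scoresTest[[ref]],
                                   te$labels)
            compRows[[paste(rc, ref)]] <- data.frame(
                model = rc, reference = ref, aucModel = dl$aucA,
                aucReference = dl$aucB, delta = dl$delta, z = dl$z,
                p = dl$p)
        }
    }

    ## single-marker threshold classifiers: Youden on validation, test eval
    markerRows <- list()
    for (mk in proteinFeatureNames()) {
        thrM <- youdenThreshold(va$proteins[[mk]], va$labels)
        if (thrM$threshold == -Inf) thrM$threshold <- min(va$proteins[[mk]])
        if (thrM$threshold == Inf)
            thrM$threshold <- max(va$proteins[[mk]]) + 1
        cls <- markerThresholdClassifier(te$proteins[[mk]], te$meta,
                                         thrM$threshold)
        ov <- cls$report$overall
        row <- data.frame(
            marker = mk, threshold = thrM$threshold, auc = cls$auc,
            sensitivity = ov$estimate[ov$metric == "sensitivity"],
            specificity = ov$estimate[ov$metric == "specificity"])
        for (ref in refNames) {
            dl <- delongPairedTest(te$proteins[[mk]], scoresTest[[ref]],
                                   te$labels)
            row[[paste0("p_vs_", ref)]] <- dl$p
        }
        markerRows[[mk]] <- row
    }
    if (length(compRows)) {
        comparisons <- do.call(rbind, compRows)
        rownames(comparisons) <- NULL
    }
    markers <- do.call(rbind, markerRows)
    rownames(markers) <- NULL

    manifest <- list(
        seed = seed, fractions = as.list(fractions),
        recipes = recipes, nComponents = nComponents, alpha = alpha,
        splitSizes = as.list(table(meta$split)),
        thresholds = lapply(thresholds, `[[`, "threshold"),
        chosenFeatures = lapply(models, function(m) m@features),
        version = as.character(utils::packageVersion("cfMotifScreen")))
    run <- structure(list(meta = meta, models = models,
                          thresholds = thresholds, evaluations = evals,
                          comparisons = comparisons, markers = markers,
                          baseline = baseline, scoresTest = scoresTest,
                          scoresVal = scoresVal, manifest = manifest),
                     class = "ScreenRun")
    if (!is.null(outDir)) writeRunReports(run, outDir)
    run
}

#' @export
print.ScreenRun <- function(x, ...) {
    cat("ScreenRun:", nrow(x$meta), "samples; splits",
        paste(names(x$manifest$splitSizes),
              unlist(x$manifest$splitSizes), sep = "=", collapse = ", "),
        "\n")
    for (rc in names(x$evaluations)) {
        a <- x$evaluations[[rc]]$auc
        cat(sprintf("  %-8s test AUC %.3f (%.3f-%.3f), threshold %.3f, %d features\n",
                    rc, a$auc, a$ci[1], a$ci[2],
                    x$thresholds[[rc]]$threshold,
                    length(x$models[[rc]]@features)))
    }
    invisible(x)
}

#' Write the reports of a pipeline run to disk
#'
#' Emits TSV tables (baseline comparability, model comparisons, marker
#' table, per-recipe screening reports, CV traces, importances) and a
#' JSON manifest naming every artefact.
#'
#' @param run a `ScreenRun` from [runPipeline()]
#' @param outDir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
writeRunReports <- function(run, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) {
        p <- file.path(outDir, name)
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
    }
    paths <- c(
        baseline = wt(run$baseline, "baseline_comparability.tsv"),
        comparisons = wt(run$comparisons, "model_comparisons.tsv"),
        markers = wt(run$markers, "marker_classifiers.tsv"),
        meta = wt(run$meta, "cohort_splits.tsv"))
    for (rc in names(run$models)) {
        m <- run$models[[rc]]
        paths[paste0(rc, "_importance")] <- wt(
            data.frame(feature = names(m@importance),
                       importance = m@importance),
            paste0(rc, "_importance.tsv"))
        if (!is.null(m@rfe))
            paths[paste0(rc, "_cvtrace")] <- wt(
                m@rfe@cvTrace, paste0(rc, "_rfe_trace.tsv"))
        rep <- run$evaluations[[rc]]$report
        paths[paste0(rc, "_screening")] <- wt(
            rbind(rep$overall, rep$subgroups),
            paste0(rc, "_screening.tsv"))
    }
    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(
        c(run$manifest, list(artefacts = as.list(paths))),
        mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(mf)
}
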