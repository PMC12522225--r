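test_that("quota allocation reproduces the reference cohort partition", {
    meta <- data.frame(sample_id = sprintf("S%03d", 1:491))
    out <- splitCohort(meta, seed = 1, stratifyBy = NULL)
    expect_equal(unname(table(out$split)),
                 c(240L, 103L, 148L), ignore_attr = TRUE)
})

test_that("splits are disjoint, exhaustive and seed-deterministic", {
    cfg <- tinyConfig(seed = 10)
    meta <- generateMetadata(cfg)
    a <- splitCohort(meta, seed = 5)
    b <- splitCohort(meta, seed = 5)
    expect_identical(a$split, b$split)
    expect_false(anyNA(a$split))
    expect_equal(sum(table(a$split)), nrow(meta))
    c2 <- splitCohort(meta, seed = 6)
    expect_false(identical(a$split, c2$split))  # seed matters
})

test_that("tiny strata fall back to a pooled global draw with a warning", {
    meta <- generateMetadata(simulationConfig(
        nPerSubgroup = c(Health = 30, Benign = 30, StageI = 2), seed = 2))
    expect_warning(out <- splitCohort(meta, seed = 3), "StageI")
    expect_false(anyNA(out$split))
})

test_that("fraction validation rejects malformed splits", {
    meta <- data.frame(sample_id = letters)
    expect_error(splitCohort(meta, fractions = c(a = 0.5, b = 0.6),
                             seed = 1, stratifyBy = NULL), "sum to 1")
    expect_error(splitCohort(meta, seed = 1), "not in metadata")
})

test_that("baseline report reproduces published comparability statistics", {
    ## rebuild a per-sample table whose cross-tabulations equal the
    ## published baseline contingency tables, then feed it back through
    tabs <- referenceBaselineTables()
    splits <- c("train", "validation", "test")
    expand <- function(m) {
        data.frame(
            level = rep(rep(rownames(m), ncol(m)), as.vector(m)),
            split = rep(rep(splits, each = nrow(m)), as.vector(m)))
    }
    want <- c(sex = 0.93, smoking = 4.50, drinking = 2.13, group = 7.26,
              subgroup = 11.90)
    for (cv in names(want)) {
        df <- expand(tabs[[cv]])
        names(df)[1] <- cv
        df$split <- factor(df$split, levels = splits)
        rep <- baselineReport(df, categorical = cv, numeric = character(0))
        expect_equal(round(rep$statistic, 2), unname(want[cv]),
                     info = cv)
    }
})

test_that("a covariate constant across splits gives chi-square 0", {
    meta <- data.frame(sex = rep("male", 60),
                       split = factor(rep(c("train", "validation", "test"),
                                          20)))
    ## single-level covariate collapses; use a 2-level one distributed
    ## identically across splits
    meta$sex <- rep(c("male", "female"), 30)
    rep <- baselineReport(meta, categorical = "sex", numeric = character(0))
    expect_equal(rep$statistic, 0)
})

test_that("absent covariates are skipped with a note", {
    meta <- data.frame(sex = rep(c("m", "f"), 30),
                       split = factor(rep(c("train", "validation", "test"),
                                          each = 20)))
    rep <- baselineReport(meta, categorical = c("sex", "ghost"),
                          numeric = character(0))
    expect_equal(nrow(rep), 1)
    expect_match(attr(rep, "notes"), "ghost")
})

test_that("random splits are comparable at the nominal rate", {
    cfg <- tinyConfig(seed = 14, nPerSubgroup = c(
        Health = 20, Benign = 20, LGIN = 10, HGIN = 10, StageI = 20,
        StageII = 10, StageIII = 10, StageIV = 10))
    meta <- generateMetadata(cfg)
    ps <- unlist(lapply(1:20, function(s) {
        m <- splitCohort(meta, seed = 1000 + s)
        baselineReport(m)$p
    }))
    expect_lt(mean(ps < 0.05), 0.15)  # ~5% nominal
})

test_that("the pipeline run is internally consistent and reproducible", {
    cfg <- simulationConfig(nPerSubgroup = twoArmCounts(40),
                            fragmentsMean = 5000, seed = 71)
    run <- suppressWarnings(
        runPipeline(simConfig = cfg, seed = 71, nFolds = 5, rfeTrees = 50,
                    hyperGrid = data.frame(num.trees = 100)))
    ## structural contract: three models, thresholds in (0, 1), tables
    expect_setequal(names(run$models), c("motif", "protein", "combined"))
    for (rc in names(run$models)) {
        thr <- run$thresholds[[rc]]$threshold
        expect_true(thr > 0 && thr < 1)
        ## reported threshold equals Youden on the validation scores
        y <- youdenThreshold(run$scoresVal[[rc]],
                             run$meta$group[run$meta$split == "validation"]
                             != "control")
        if (is.finite(y$threshold))
            expect_equal(thr, y$threshold)
    }
    expect_equal(nrow(run$markers), 10)
    expect_true(all(c("model", "reference", "p") %in%
                    names(run$comparisons)))
    ## self-comparisons are exact ties
    self <- run$comparisons[run$comparisons$model ==
                            run$comparisons$reference, ]
    expect_true(all(self$p == 1))
    ## rerun under the same seed reproduces the scores exactly
    run2 <- suppressWarnings(
        runPipeline(simConfig = cfg, seed = 71, nFolds = 5, rfeTrees = 50,
                    hyperGrid = data.frame(num.trees = 100)))
    expect_identical(run$scoresTest, run2$scoresTest)
    expect_identical(run$manifest$thresholds, run2$manifest$thresholds)
})

test_that("no fitted state depends on validation or test samples", {
    cfg <- simulationConfig(nPerSubgroup = twoArmCounts(40),
                            fragmentsMean = 3000, seed = 81)
    meta <- generateMetadata(cfg)
    me <- generateMotifCounts(meta, cfg)
    prot <- generateProteinPanel(meta, cfg)
    meta <- suppressWarnings(splitCohort(meta, seed = 81))
    tr <- meta$split == "train"
    fit1 <- buildRecipe("motif", motifs = countsToRatios(me)[, tr],
                        labels = meta$group[tr] != "control",
                        nFolds = 5, rfeTrees = 50, seed = 2)
    ## perturb every non-training sample and refit identically
    cnt <- motifCounts(me)
    cnt[, !tr] <- cnt[, rev(which(!tr))]
    me2 <- MotifExperiment(cnt, colData = meta)
    fit2 <- buildRecipe("motif", motifs = countsToRatios(me2)[, tr],
                        labels = meta$group[tr] != "control",
                        nFolds = 5, rfeTrees = 50, seed = 2)
    expect_identical(modelFeatures(fit1), modelFeatures(fit2))
    expect_identical(featureImportance(fit1), featureImportance(fit2))
    expect_identical(fit1@scaler@mean, fit2@scaler@mean)
})

test_that("run reports serialise to TSV and a manifest", {
    cfg <- simulationConfig(nPerSubgroup = twoArmCounts(30),
                            fragmentsMean = 2000, seed = 91)
    d <- tempfile()
    run <- suppressWarnings(
        runPipeline(simConfig = cfg, seed = 91, nFolds = 4, rfeTrees = 50,
                    hyperGrid = data.frame(num.trees = 100),
                    recipes = c("protein"), outDir = d))
    expect_true(file.exists(file.path(d, "manifest.json")))
    mf <- jsonlite::read_json(file.path(d, "manifest.json"))
    for (p in unlist(mf$artefacts)) expect_true(file.exists(p))
    tab <- read.delim(file.path(d, "protein_screening.tsv"))
    expect_true(all(c("metric", "estimate", "lower", "upper") %in%
                    names(tab)))
})
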