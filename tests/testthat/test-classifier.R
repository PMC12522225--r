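test_that("stratified folds keep both classes in every fold", {
    case <- rep(c(TRUE, FALSE), c(30, 50))
    f <- stratifiedFolds(case, 10, seed = 2)
    for (k in 1:10) {
        expect_true(any(case[f == k]))
        expect_true(any(!case[f == k]))
    }
    expect_identical(f, stratifiedFolds(case, 10, seed = 2))
    expect_error(stratifiedFolds(case, 1), ">= 2")
})

test_that("single-feature RFE chooses that feature", {
    withr::with_seed(4, {
        x <- data.frame(f1 = c(rnorm(30, 2), rnorm(30)))
        lab <- rep(c(TRUE, FALSE), each = 30)
    })
    r <- rfeSelect(x, lab, nFolds = 5, numTrees = 50, seed = 1)
    expect_equal(r@chosen, "f1")
    expect_equal(r@ranking, "f1")
})

test_that("RFE ranks planted informative features above pure noise", {
    withr::with_seed(19, {
        n <- 150
        lab <- rep(c(TRUE, FALSE), each = n / 2)
        inf <- sapply(1:3, function(i) ifelse(lab, 2, 0) + rnorm(n))
        noise <- matrix(rnorm(n * 17), n)
        x <- data.frame(inf, noise)
        colnames(x) <- c(paste0("sig", 1:3), paste0("noise", 1:17))
    })
    r <- rfeSelect(x, lab, nFolds = 5, numTrees = 100, seed = 7)
    ranks <- match(c(paste0("sig", 1:3)), r@ranking)
    expect_true(all(ranks <= 3))          # informative on top
    expect_true(all(paste0("sig", 1:3) %in% r@chosen))
    ## the chosen size is the smallest argmax of the CV trace
    tr <- r@cvTrace
    best <- max(tr$meanAUC)
    expect_equal(length(r@chosen),
                 min(tr$size[abs(tr$meanAUC - best) < 1e-12]))
    ## ranking is a permutation of the inputs
    expect_setequal(r@ranking, colnames(x))
})

test_that("RFE ranking is invariant to feature column order", {
    withr::with_seed(23, {
        x <- data.frame(a = rnorm(60) + rep(c(1, 0), each = 30),
                        b = rnorm(60), c = rnorm(60))
        lab <- rep(c(TRUE, FALSE), each = 30)
    })
    r1 <- rfeSelect(x, lab, nFolds = 5, numTrees = 50, seed = 3)
    r2 <- rfeSelect(x[, c(3, 1, 2)], lab, nFolds = 5, numTrees = 50,
                    seed = 3)
    expect_identical(r1@ranking, r2@ranking)
    expect_identical(r1@chosen, r2@chosen)
})

test_that("forest fit is deterministic and separates a perfect feature", {
    withr::with_seed(8, {
        x <- data.frame(f = c(rnorm(25, 6), rnorm(25)))
        lab <- rep(c(TRUE, FALSE), each = 25)
    })
    m1 <- fitRandomForest(x, lab, nFolds = 5, seed = 9)
    m2 <- fitRandomForest(x, lab, nFolds = 5, seed = 9)
    s1 <- predictScores(m1, features = x)
    expect_identical(s1, predictScores(m2, features = x))
    expect_equal(aucScore(s1, lab), 1.0)
    expect_true(all(s1 >= 0 & s1 <= 1))
    ## importances normalised
    expect_equal(sum(featureImportance(m1)), 1)
})

test_that("permuted labels give chance-level CV AUC", {
    withr::with_seed(41, {
        x <- data.frame(matrix(rnorm(200 * 5), 200))
        lab <- sample(rep(c(TRUE, FALSE), each = 100))
    })
    m <- fitRandomForest(x, lab, seed = 5)
    expect_gt(mean(m@cvScores), 0.4)
    expect_lt(mean(m@cvScores), 0.6)
})

test_that("duplicated samples score identically and scores are bounded", {
    withr::with_seed(2, {
        x <- data.frame(matrix(rnorm(40 * 3), 40))
        lab <- rep(c(TRUE, FALSE), 20)
    })
    m <- fitRandomForest(x, lab, nFolds = 5, seed = 1)
    dup <- rbind(x[1, ], x[1, ])
    s <- predictScores(m, features = dup)
    expect_equal(s[[1]], s[[2]])
})

test_that("protein recipe recovers exactly-planted markers", {
    ## exactly three markers carry signal; the rest are pure noise
    pp <- defaultProteinParams(shift = 1)
    planted <- c("CEA", "Cyfra21-1", "SCC")
    pp$shift_ESCC[pp$marker %in% planted] <- 2.5
    pp$shift_ESPL[pp$marker %in% planted] <- 2.5
    cfg <- simulationConfig(
        nPerSubgroup = c(Benign = 75, StageII = 75),
        proteinParams = pp, seed = 17, fragmentsMean = 200)
    meta <- generateMetadata(cfg)
    prot <- generateProteinPanel(meta, cfg)
    mod <- buildRecipe("protein", proteins = prot,
                       labels = meta$group != "control",
                       nFolds = 5, rfeTrees = 100, seed = 3)
    expect_true(all(planted %in% modelFeatures(mod)))
})

test_that("combined recipe keeps protein features when only proteins carry signal", {
    cfg <- simulationConfig(
        nPerSubgroup = c(Benign = 60, StageI = 60), effectDelta = 0,
        proteinParams = defaultProteinParams(shift = 2.5),
        fragmentsMean = 2000, seed = 29)
    meta <- generateMetadata(cfg)
    me <- countsToRatios(generateMotifCounts(meta, cfg))
    prot <- generateProteinPanel(meta, cfg)
    mod <- buildRecipe("combined", motifs = me, proteins = prot,
                       labels = meta$group != "control",
                       nFolds = 5, rfeTrees = 100, seed = 3)
    expect_gte(sum(modelFeatures(mod) %in% proteinFeatureNames()), 1)
})

test_that("motif recipe scores order disease severity on planted cohorts", {
    cfg <- simulationConfig(nPerSubgroup = twoArmCounts(60),
                            fragmentsMean = 20000, seed = 37)
    meta <- generateMetadata(cfg)
    me <- countsToRatios(generateMotifCounts(meta, cfg))
    mod <- buildRecipe("motif", motifs = me,
                       labels = meta$group != "control",
                       nFolds = 5, rfeTrees = 100, seed = 5)
    sc <- predictScores(mod, motifs = me)
    late <- meta$subgroup %in% c("StageIII", "StageIV")
    expect_gt(mean(sc[late]), mean(sc[meta$group == "control"]))
})

test_that("recipes demand their omic layers", {
    expect_error(buildRecipe("motif", labels = c(TRUE, FALSE)),
                 "motif layer")
    expect_error(buildRecipe("protein", labels = c(TRUE, FALSE)),
                 "protein layer")
})
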