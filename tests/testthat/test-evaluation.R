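test_that("AUC equals exhaustive pair counting on the worked example", {
    sc <- c(0.1, 0.4, 0.35, 0.8)
    lab <- c(FALSE, FALSE, TRUE, TRUE)
    expect_equal(aucScore(sc, lab), 0.75)  # 3 of 4 pairs won
    expect_equal(aucScore(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
    expect_equal(aucScore(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
    expect_error(aucScore(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC matches pair counting and the ROC trapezoid on random instances", {
    withr::with_seed(101, {
        for (i in 1:60) {
            n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
            sc <- round(rnorm(n1 + n0), sample(c(1, 2, Inf), 1))
            lab <- rep(c(TRUE, FALSE), c(n1, n0))
            a <- aucScore(sc, lab)
            expect_equal(a, pairCountAuc(sc, lab))
            expect_equal(a, rocAuc(rocCurve(sc, lab)), tolerance = 1e-9)
        }
    })
})

test_that("ROC endpoints and monotonicity hold", {
    withr::with_seed(9, {
        sc <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
    })
    roc <- rocCurve(sc, lab)
    expect_equal(roc$sensitivity[1], 1)
    expect_equal(roc$specificity[1], 0)
    expect_equal(roc$sensitivity[nrow(roc)], 0)
    expect_equal(roc$specificity[nrow(roc)], 1)
    expect_true(all(diff(roc$sensitivity) <= 0))
    expect_true(all(diff(roc$specificity) >= 0))
})

test_that("DeLong point estimate and degenerate cases behave", {
    withr::with_seed(2, b <- binormalScores(30, 30, 1))
    est <- delongCi(b$scores, b$labels)
    expect_equal(est$auc, aucScore(b$scores, b$labels))
    expect_true(est$ci[1] <= est$auc && est$auc <= est$ci[2])
    ## perfect separation: variance 0, CI clips to (1, 1)
    sep <- delongCi(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
    expect_equal(sep$variance, 0)
    expect_equal(sep$ci, c(1, 1))
    expect_false(sep$degenerate)
})

test_that("DeLong SE agrees with a bootstrap oracle on a seeded instance", {
    withr::with_seed(60, b <- binormalScores(30, 30, 1.2))
    est <- delongCi(b$scores, b$labels)
    case <- b$labels
    boots <- withr::with_seed(61, vapply(1:10000, function(i) {
        ic <- sample(which(case), replace = TRUE)
        in0 <- sample(which(!case), replace = TRUE)
        aucScore(b$scores[c(ic, in0)],
                 rep(c(TRUE, FALSE), c(length(ic), length(in0))))
    }, numeric(1)))
    expect_lt(abs(sqrt(est$variance) - sd(boots)) / sd(boots), 0.15)
})

test_that("DeLong variance agrees with pROC's implementation", {
    skip_if_not_installed("pROC")
    withr::with_seed(14, b <- binormalScores(40, 50, 0.8))
    est <- delongCi(b$scores, b$labels)
    pr <- pROC::roc(response = b$labels, predictor = b$scores,
                    quiet = TRUE, direction = "<")
    expect_equal(est$auc, as.numeric(pROC::auc(pr)))
    expect_equal(unname(est$ci),
                 as.numeric(pROC::ci.auc(pr, method = "delong"))[c(1, 3)],
                 tolerance = 1e-9)
})

test_that("paired DeLong test: self-comparison, antisymmetry, power", {
    withr::with_seed(30, {
        lab <- rep(c(TRUE, FALSE), each = 100)
        a <- as.numeric(lab) + rnorm(200)
        b <- rnorm(200)
    })
    self <- delongPairedTest(a, a, lab)
    expect_equal(self$delta, 0)
    expect_equal(self$p, 1)
    ab <- delongPairedTest(a, b, lab)
    ba <- delongPairedTest(b, a, lab)
    expect_equal(ab$delta, -ba$delta)
    expect_equal(ab$z, -ba$z)
    expect_equal(ab$p, ba$p)
    expect_lt(ab$p, 0.01)
    expect_error(delongPairedTest(a[1:10], b, lab), "unpaired")
})

test_that("paired DeLong agrees with pROC and a permutation oracle on rejection", {
    withr::with_seed(33, {
        lab <- rep(c(TRUE, FALSE), each = 100)
        a <- as.numeric(lab) + rnorm(200)
        b <- rnorm(200)
    })
    ours <- delongPairedTest(a, b, lab)
    skip_if_not_installed("pROC")
    pr <- pROC::roc.test(
        pROC::roc(lab, a, quiet = TRUE, direction = "<"),
        pROC::roc(lab, b, quiet = TRUE, direction = "<"),
        method = "delong", paired = TRUE)
    expect_equal(ours$p, pr$p.value, tolerance = 1e-9)
    ## permutation oracle: swap model identity per sample under H0
    d0 <- abs(aucScore(a, lab) - aucScore(b, lab))
    perm <- withr::with_seed(34, vapply(1:500, function(i) {
        sw <- runif(200) < 0.5
        pa <- ifelse(sw, b, a); pb <- ifelse(sw, a, b)
        abs(aucScore(pa, lab) - aucScore(pb, lab))
    }, numeric(1)))
    expect_lt(mean(perm >= d0), 0.01)  # both routes reject
})

test_that("Youden threshold: separable case, ties, brute-force equality", {
    y <- youdenThreshold(c(0.2, 0.3, 0.7, 0.8),
                         c(FALSE, FALSE, TRUE, TRUE))
    expect_equal(y$threshold, 0.5)  # midpoint convention
    expect_equal(y$J, 1)
    flat <- youdenThreshold(rep(1, 6), rep(c(TRUE, FALSE), 3))
    expect_equal(flat$J, 0)
    withr::with_seed(77, {
        for (i in 1:200) {
            n <- sample(4:40, 1)
            sc <- round(rnorm(n), sample(c(1, 2), 1))
            lab <- c(TRUE, FALSE, runif(n - 2) < 0.5)
            got <- youdenThreshold(sc, lab)
            want <- bruteYouden(sc, lab)
            expect_equal(got$threshold, want$threshold)
            expect_equal(got$J, want$J)
        }
    })
})

test_that("Wald proportion CIs reproduce the printed screening intervals", {
    ci <- proportionCi(25, 26)
    expect_equal(round(unname(ci["estimate"]), 1), 96.2)
    expect_equal(round(unname(ci["lower"]), 1), 88.8)
    expect_equal(unname(ci["upper"]), 100)  # clipped
    ci2 <- proportionCi(10, 11)
    expect_equal(round(unname(ci2["lower"]), 1), 73.9)
    expect_equal(unname(proportionCi(5, 5)["upper"]), 100)
    ## Wilson alternative stays inside [0, 100] without clipping
    w <- proportionCi(25, 26, method = "wilson")
    expect_lt(unname(w["upper"]), 100)
})

test_that("screening metrics assemble sensitivity, specificity and confusion", {
    meta <- data.frame(
        group = rep(c("ESPL", "control"), c(26, 20)),
        subgroup = rep(c("LGIN", "Benign"), c(26, 20)))
    sc <- c(rep(0.8, 25), 0.1, rep(0.2, 15), rep(0.9, 5))
    rep1 <- screeningMetrics(sc, meta, 0.5)
    ov <- rep1$overall
    expect_equal(ov$k[ov$metric == "sensitivity"], 25)
    expect_equal(round(ov$estimate[ov$metric == "sensitivity"], 1), 96.2)
    expect_equal(round(ov$lower[ov$metric == "sensitivity"], 1), 88.8)
    expect_equal(ov$estimate[ov$metric == "specificity"], 75)
    expect_equal(sum(rep1$confusion), 46)
    expect_true(any(grepl("HGIN", rep1$notes)))  # empty subgroup noted
    ## threshold above every score
    rep2 <- screeningMetrics(sc, meta, 2)
    expect_equal(rep2$overall$estimate, c(0, 100))
})

test_that("marker threshold classifier handles direction and missing values", {
    meta <- data.frame(group = rep(c("ESCC", "control"), each = 10),
                       subgroup = rep(c("StageI", "Health"), each = 10))
    withr::with_seed(6, v <- c(rnorm(10, 5), rnorm(10, 1)))
    thrAll <- min(v) - 1
    hi <- markerThresholdClassifier(v, meta, thrAll)  # everything positive
    expect_equal(hi$report$overall$estimate, c(100, 0))
    lo <- markerThresholdClassifier(v, meta, thrAll, "low_is_positive")
    expect_equal(lo$calls, !hi$calls)
    v2 <- v; v2[c(1, 15)] <- NA
    mm <- markerThresholdClassifier(v2, meta, 2)
    expect_equal(mm$nMissing, 2)
})

test_that("marker AUC matches the binormal closed form on the log scale", {
    ## lognormal shift 1.5 with sdlog 0.5 per arm:
    ## AUC = Phi(log(1.5) / sqrt(0.5^2 + 0.5^2))
    withr::with_seed(55, {
        v <- c(rlnorm(200, log(2) + log(1.5), 0.5), rlnorm(200, log(2), 0.5))
    })
    lab <- rep(c(TRUE, FALSE), each = 200)
    want <- pnorm(log(1.5) / sqrt(2 * 0.5^2))
    expect_equal(aucScore(v, lab), want, tolerance = 0.05)
})

test_that("chi-square wrapper reproduces textbook and degenerate results", {
    flat <- chisqIndependence(matrix(10, 2, 2))
    expect_equal(flat$statistic, 0)
    expect_equal(flat$p, 1)
    sex <- rbind(c(149, 69, 97), c(91, 34, 51))
    cs <- chisqIndependence(sex)
    expect_equal(round(cs$statistic, 2), 0.93)
    expect_equal(cs$df, 2)
    expect_error(chisqIndependence(matrix(c(1, 0, 2, 0), 2)), "margin")
    expect_error(chisqIndependence(matrix(1:2, 2, 1)), "2x2")
    ## Yates correction only for 2x2
    y <- chisqIndependence(rbind(c(12, 5), c(6, 14)), correction = TRUE)
    expect_equal(y$statistic,
                 unname(chisq.test(rbind(c(12, 5), c(6, 14)))$statistic))
})

test_that("Kruskal-Wallis matches the hand computation and permutation null", {
    same <- kruskalWallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
    expect_equal(same$statistic, 0)
    kw <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
    expect_equal(round(kw$statistic, 3), 3.857)  # R1 = 6, R2 = 15
    expect_equal(kw$statistic,
                 unname(kruskal.test(c(1:6), rep(c("a", "b"),
                                                 each = 3))$statistic))
    ## permutation oracle on a seeded instance
    withr::with_seed(88, {
        v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
    })
    obs <- kruskalWallis(v, g)
    perm <- withr::with_seed(89, vapply(1:4000, function(i)
        kruskal.test(v, sample(g))$statistic, numeric(1)))
    expect_equal(obs$p, mean(perm >= obs$statistic), tolerance = 0.03)
})
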