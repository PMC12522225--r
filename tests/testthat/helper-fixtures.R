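## Shared fixture builders: every fixture is generated in code.

## small, fast simulation config covering all eight subgroups
tinyConfig <- function(seed = 1L, nPerSubgroup = c(
                           Health = 6, Benign = 8, LGIN = 4, HGIN = 4,
                           StageI = 8, StageII = 4, StageIII = 4,
                           StageIV = 4),
                       fragmentsMean = 400, ...) {
    simulationConfig(nPerSubgroup = nPerSubgroup,
                     fragmentsMean = fragmentsMean, seed = seed, ...)
}

## binormal scores: n1 cases at N(mu, 1), n0 controls at N(0, 1)
binormalScores <- function(n1, n0, mu) {
    list(scores = c(rnorm(n1, mu), rnorm(n0)),
         labels = rep(c(TRUE, FALSE), c(n1, n0)))
}

## exhaustive pair-counting AUC oracle (ties count 1/2)
pairCountAuc <- function(scores, case) {
    x <- scores[case]; y <- scores[!case]
    wins <- 0
    for (xi in x) wins <- wins + sum(xi > y) + 0.5 * sum(xi == y)
    wins / (length(x) * length(y))
}

## brute-force Youden oracle: every midpoint + sentinels, explicit
## tie-break toward higher sensitivity then lower threshold
bruteYouden <- function(scores, case) {
    u <- sort(unique(scores))
    cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
    best <- NULL
    for (t in cand) {
        sens <- mean(scores[case] >= t)
        spec <- mean(scores[!case] < t)
        J <- sens + spec - 1
        if (is.null(best) || J > best$J ||
            (J == best$J && sens > best$sens))
            best <- list(threshold = t, J = J, sens = sens)
    }
    best
}

## minimal hand-written SAM -> sorted indexed BAM for profiler tests:
## fragments is a data.frame with columns pos (1-based leftmost) and len
writeToyBam <- function(refSeq, fragments, dir = tempfile()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ref <- Biostrings::DNAStringSet(refSeq)
    names(ref) <- "toy"
    refFile <- file.path(dir, "ref.fa")
    Biostrings::writeXStringSet(ref, refFile)
    Rsamtools::indexFa(refFile)
    rl <- 4L  # read length; fragments must be >= 2*rl? no: mates may overlap
    lines <- c("@HD\tVN:1.6", paste0("@SQ\tSN:toy\tLN:", nchar(refSeq)))
    qual <- paste(rep("I", rl), collapse = "")
    for (i in seq_len(nrow(fragments))) {
        p1 <- fragments$pos[i]
        len <- fragments$len[i]
        p2 <- p1 + len - rl
        s1 <- substring(refSeq, p1, p1 + rl - 1)
        s2 <- substring(refSeq, p2, p2 + rl - 1)
        qn <- sprintf("frag%03d", i)
        lines <- c(lines,
                   paste(qn, 99L, "toy", p1, 60L, paste0(rl, "M"), "=",
                         p2, len, s1, qual, sep = "\t"),
                   paste(qn, 147L, "toy", p2, 60L, paste0(rl, "M"), "=",
                         p1, -len, s2, qual, sep = "\t"))
    }
    sam <- file.path(dir, "toy.sam")
    writeLines(lines, sam)
    bam <- Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                            indexDestination = TRUE)
    list(bam = bam, reference = refFile, refSeq = refSeq)
}

## permissive profiler config for toy fragments
toyProfilerConfig <- function(...)
    profilerConfig(minFragmentLength = 5L, maxFragmentLength = 100L,
                   minMappingQuality = 0L, minUsableFragments = 1L, ...)
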