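## Synthetic cohort generator.  Emulates the statistical structure the
## downstream analysis assumes -- a three-group cohort (control / ESPL /
## ESCC) with eight lesion subgroups, Dirichlet-multinomial end-motif
## counts with a planted up/down motif effect that strengthens with lesion
## severity, and log-normal protein panels with group-level upshifts in
## CEA, Cyfra21-1, PG I and PG II.

.pkgCache <- new.env(parent = emptyenv())

## Frozen internal seed: the baseline motif probability vector and the
## planted up/down motif identities are identical on every install.
.FROZEN_SEED <- 20211201L

#' Baseline end-motif probability vector
#'
#' A single fixed 256-long probability vector drawn once from a symmetric
#' Dirichlet (concentration 50) under a frozen internal seed, so the
#' synthetic ground truth is identical across installs and sessions.
#'
#' @return named numeric vector over the 256 motifs, summing to 1
#' @export
baselineMotifProbs <- function() {
    if (is.null(.pkgCache$baseline)) {
        .pkgCache$baseline <- withSeed(.FROZEN_SEED, {
            p <- rdirichlet1(rep(50, 256))
            names(p) <- enumerateMotifs(4L)
            p
        })
    }
    .pkgCache$baseline
}

## Frozen permutation of 1:256 used to pick planted up/down motif sets.
plantedMotifIndices <- function(nUp, nDown) {
    if (is.null(.pkgCache$perm))
        .pkgCache$perm <- withSeed(.FROZEN_SEED + 1L, sample.int(256L))
    perm <- .pkgCache$perm
    motifs <- enumerateMotifs(4L)
    list(up = sort(motifs[perm[seq_len(nUp)]]),
         down = sort(motifs[perm[nUp + seq_len(nDown)]]))
}

#' Default protein panel parameters
#'
#' Log-normal location/scale per measured marker plus multiplicative
#' group shifts.  By default CEA, Cyfra21-1, PG I and PG II are shifted up
#' in the ESPL and ESCC groups (`shift` for ESCC, a slightly attenuated
#' shift for ESPL); all other markers are unshifted.  Locations are typical
#' serum concentrations (ng/mL or U/mL scale); they only set the scale of
#' the simulated panel.
#'
#' @param shift multiplicative ESCC-group shift applied to the four
#'   differential markers (default 1.5)
#' @param sdlog common log-scale standard deviation (default 0.5)
#' @return data.frame with columns marker, meanlog, sdlog, shift_ESPL,
#'   shift_ESCC
#' @export
defaultProteinParams <- function(shift = 1.5, sdlog = 0.5) {
    stopifnot(shift > 0, sdlog > 0)
    markers <- proteinMarkers()
    loc <- c(AFP = 3, `CA19-9` = 10, `CA24-2` = 5, `CA72-4` = 2, CEA = 2,
             `Cyfra21-1` = 2, SCC = 1, PGI = 50, PGII = 8)
    up <- c("CEA", "Cyfra21-1", "PGI", "PGII")
    data.frame(
        marker = markers,
        meanlog = log(unname(loc[markers])),
        sdlog = sdlog,
        shift_ESPL = ifelse(markers %in% up, 1 + 0.75 * (shift - 1), 1),
        shift_ESCC = ifelse(markers %in% up, shift, 1),
        stringsAsFactors = FALSE)
}

#' Subgroup sizes for a balanced two-arm cohort
#'
#' Desk-scale default: `nPerArm` controls (30% healthy, 70% benign) versus
#' `nPerArm` cases spread over LGIN..StageIV in the proportions of the
#' reference cohort (which is dominated by stage I disease).
#'
#' @param nPerArm samples per arm (default 200)
#' @return named integer vector over the eight subgroups
#' @export
twoArmCounts <- function(nPerArm = 200L) {
    nPerArm <- as.integer(nPerArm)
    ctrl <- c(Health = round(0.3 * nPerArm))
    ctrl["Benign"] <- nPerArm - ctrl["Health"]
    mix <- c(LGIN = 46, HGIN = 45, StageI = 124, StageII = 23,
             StageIII = 35, StageIV = 17) / 290
    case <- floor(mix * nPerArm)
    rem <- nPerArm - sum(case)
    frac <- mix * nPerArm - case
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    case[add] <- case[add] + 1
    out <- c(ctrl, case)
    storage.mode(out) <- "integer"
    out[subgroupLevels()]
}

#' Build a simulation configuration
#'
#' Assembles a validated [SimulationConfig-class].  Defaults follow the
#' reference cohort structure: 75 planted up-motifs and 128 down-motifs, a
#' severity gradient rising from LGIN (0.5) to stage IV (1.0), 50,000
#' fragments per sample on average, and a protein panel with upshifted
#' CEA, Cyfra21-1, PG I and PG II in case groups.
#'
#' @param nPerSubgroup named vector of samples per subgroup (default: the
#'   reference cohort's 491-sample composition)
#' @param nUpMotifs,nDownMotifs planted motif counts (defaults 75 / 128)
#' @param effectDelta log-scale probability shift on planted motifs
#'   (default 0.3; 0 gives a null cohort)
#' @param severityScaling named multipliers per subgroup; must be
#'   non-decreasing from LGIN to StageIV
#' @param dirichletConcentration between-sample variability control
#'   (default 2000; larger = tighter around the subgroup mean profile)
#' @param fragmentsMean,fragmentsDispersion negative-binomial mean and size
#'   for per-sample fragment totals (defaults 50000, 20)
#' @param proteinParams see [defaultProteinParams()]
#' @param seed integer seed
#' @return a validated [SimulationConfig-class]
#' @examples
#' cfg <- simulationConfig(nPerSubgroup = c(Health = 5, StageI = 5), seed = 1)
#' @export
simulationConfig <- function(nPerSubgroup = c(
                                 Health = 29L, Benign = 172L, LGIN = 46L,
                                 HGIN = 45L, StageI = 124L, StageII = 23L,
                                 StageIII = 35L, StageIV = 17L),
                             nUpMotifs = 75L, nDownMotifs = 128L,
                             effectDelta = 0.3,
                             severityScaling = c(
                                 Health = 0, Benign = 0, LGIN = 0.5,
                                 HGIN = 0.6, StageI = 0.7, StageII = 0.8,
                                 StageIII = 0.9, StageIV = 1.0),
                             dirichletConcentration = 2000,
                             fragmentsMean = 50000,
                             fragmentsDispersion = 20,
                             proteinParams = defaultProteinParams(),
                             seed = 1L) {
    full <- setNames(integer(length(subgroupLevels())), subgroupLevels())
    full[names(nPerSubgroup)] <- as.integer(nPerSubgroup)
    sev <- setNames(numeric(length(subgroupLevels())), subgroupLevels())
    sev[names(severityScaling)] <- severityScaling
    new("SimulationConfig",
        nPerSubgroup = full, nUpMotifs = as.integer(nUpMotifs),
        nDownMotifs = as.integer(nDownMotifs), effectDelta = effectDelta,
        severityScaling = sev,
        dirichletConcentration = dirichletConcentration,
        fragmentsMean = fragmentsMean,
        fragmentsDispersion = fragmentsDispersion,
        proteinParams = proteinParams, seed = as.integer(seed))
}

#' Generate cohort metadata
#'
#' One row per sample with subgroup, the derived screening group
#' (Health/Benign -> control, LGIN/HGIN -> ESPL, stages -> ESCC), and
#' simple demographic covariates (age, sex, smoking, drinking) whose
#' distributions shift with group the way the reference cohort's do --
#' ESCC patients older, more often male, smokers and drinkers.  The
#' `split` column is left unassigned (`NA`) until [splitCohort()].
#'
#' @param config a [SimulationConfig-class]
#' @return data.frame (one row per sample) with columns sample_id, group,
#'   subgroup, age, sex, smoking, drinking, split
#' @export
generateMetadata <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    n <- config@nPerSubgroup
    subgroup <- factor(rep(names(n), n), levels = subgroupLevels())
    group <- subgroupToGroup(as.character(subgroup))
    total <- length(subgroup)
    withSeed(deriveSeed(config@seed, "metadata"), {
        ageMu <- c(control = 52, ESPL = 62, ESCC = 63)[as.character(group)]
        age <- pmin(90, pmax(25, round(rnorm(total, ageMu, 9))))
        pMale <- c(control = 0.40, ESPL = 0.69, ESCC = 0.87)[as.character(group)]
        sex <- ifelse(rbinom(total, 1, pMale) == 1, "male", "female")
        pSmoke <- c(control = 0.10, ESPL = 0.26, ESCC = 0.43)[as.character(group)]
        pDrink <- c(control = 0.12, ESPL = 0.32, ESCC = 0.41)[as.character(group)]
        smoke3 <- function(p) {
            u <- runif(total)
            ifelse(u < p, "smoker", ifelse(u < p + 0.08, "unknown",
                                           "non-smoker"))
        }
        smoking <- smoke3(pSmoke)
        u <- runif(total)
        drinking <- ifelse(u < pDrink, "drinker",
                           ifelse(u < pDrink + 0.08, "unknown",
                                  "non-drinker"))
        data.frame(
            sample_id = sprintf("S%04d", seq_len(total)),
            group = group, subgroup = subgroup, age = age, sex = sex,
            smoking = smoking, drinking = drinking,
            split = factor(rep(NA_character_, total),
                           levels = c("train", "validation", "test")),
            stringsAsFactors = FALSE)
    })
}

## Subgroup mean motif probability vector: baseline perturbed by
## exp(+/- severity * delta) on planted motifs, renormalised.
subgroupMeanProbs <- function(config, planted) {
    base <- baselineMotifProbs()
    lapply(setNames(nm = subgroupLevels()), function(sg) {
        s <- config@severityScaling[[sg]]
        p <- base
        p[planted$up] <- p[planted$up] * exp(s * config@effectDelta)
        p[planted$down] <- p[planted$down] * exp(-s * config@effectDelta)
        if (any(p <= 0)) stop("degenerate motif probabilities in ", sg)
        p / sum(p)
    })
}

#' Generate synthetic end-motif counts
#'
#' Per sample: the fragment total is drawn negative-binomially, a
#' sample-specific motif probability vector is drawn from a Dirichlet
#' centred on the subgroup mean vector (the frozen baseline perturbed by
#' `exp(+/- severity * effectDelta)` on the planted motifs), and counts are
#' drawn multinomially, so each row sums exactly to its drawn total.  The
#' planted up/down motif identities travel with the result as ground
#' truth.
#'
#' @param cohort metadata from [generateMetadata()]
#' @param config the same [SimulationConfig-class]
#' @return a [MotifExperiment-class] (counts assay; `colData` carries the
#'   cohort metadata; `plantedMotifs()` returns the ground truth)
#' @export
generateMotifCounts <- function(cohort, config) {
    stopifnot(is(config, "SimulationConfig"), nrow(cohort) > 0)
    planted <- plantedMotifIndices(config@nUpMotifs, config@nDownMotifs)
    means <- subgroupMeanProbs(config, planted)
    counts <- withSeed(deriveSeed(config@seed, "motif_counts"), {
        totals <- rnbinom(nrow(cohort), size = config@fragmentsDispersion,
                          mu = config@fragmentsMean)
        vapply(seq_len(nrow(cohort)), function(i) {
            p <- rdirichlet1(config@dirichletConcentration *
                                 means[[as.character(cohort$subgroup[i])]])
            as.numeric(rmultinom(1, totals[i], p))
        }, numeric(256L))
    })
    rownames(counts) <- enumerateMotifs(4L)
    colnames(counts) <- cohort$sample_id
    MotifExperiment(counts, colData = cohort, planted = planted)
}

#' Generate a synthetic protein panel
#'
#' Each of the nine measured markers is drawn log-normal per sample with a
#' group-specific multiplicative shift (shift_ESPL for precancerous
#' samples, shift_ESCC for tumours, 1 for controls); the PGR column is the
#' elementwise PG I / PG II ratio.  All values are strictly positive.
#'
#' @param cohort metadata from [generateMetadata()]
#' @param config the same [SimulationConfig-class]
#' @return data.frame with sample_id plus the ten protein features
#' @export
generateProteinPanel <- function(cohort, config) {
    stopifnot(is(config, "SimulationConfig"), nrow(cohort) > 0)
    pp <- config@proteinParams
    withSeed(deriveSeed(config@seed, "proteins"), {
        out <- data.frame(sample_id = cohort$sample_id,
                          stringsAsFactors = FALSE)
        for (j in seq_len(nrow(pp))) {
            shift <- c(control = 1, ESPL = pp$shift_ESPL[j],
                       ESCC = pp$shift_ESCC[j])[as.character(cohort$group)]
            out[[pp$marker[j]]] <- rlnorm(nrow(cohort),
                                          meanlog = pp$meanlog[j] + log(shift),
                                          sdlog = pp$sdlog[j])
        }
        out$PGR <- out$PGI / out$PGII
        out
    })
}
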