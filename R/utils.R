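## Shared vocabulary: subgroups, groups and the marker panel.

#' Lesion subgroups in severity order
#'
#' Cohort subgroups from healthy controls through benign disease,
#' low/high-grade intraepithelial neoplasia, to stage I-IV ESCC.
#' @return character vector of the eight subgroup levels
#' @export
subgroupLevels <- function()
    c("Health", "Benign", "LGIN", "HGIN",
      "StageI", "StageII", "StageIII", "StageIV")

#' @rdname subgroupLevels
#' @export
groupLevels <- function() c("control", "ESPL", "ESCC")

#' Map subgroups to screening groups
#'
#' Health and benign disease form the control group; LGIN and HGIN the
#' precancerous (ESPL) group; all tumour stages the ESCC group.
#' @param subgroup character vector of subgroup labels
#' @return factor with levels control, ESPL, ESCC
#' @export
subgroupToGroup <- function(subgroup) {
    map <- c(Health = "control", Benign = "control",
             LGIN = "ESPL", HGIN = "ESPL",
             StageI = "ESCC", StageII = "ESCC",
             StageIII = "ESCC", StageIV = "ESCC")
    bad <- setdiff(unique(subgroup), names(map))
    if (length(bad)) stop("unknown subgroup(s): ", paste(bad, collapse = ", "))
    factor(unname(map[as.character(subgroup)]), levels = groupLevels())
}

#' Measured protein markers and the derived PGR ratio
#'
#' @return for `proteinMarkers()` the nine assayed markers; for
#'   `proteinFeatureNames()` the ten model features (markers plus
#'   PGR = PG I / PG II)
#' @export
proteinMarkers <- function()
    c("AFP", "CA19-9", "CA24-2", "CA72-4", "CEA", "Cyfra21-1", "SCC",
      "PGI", "PGII")

#' @rdname proteinMarkers
#' @export
proteinFeatureNames <- function() c(proteinMarkers(), "PGR")

#' Derive a stage seed from the root seed
#'
#' One root seed fans out to per-stage seeds through a fixed integer
#' recurrence, so each pipeline stage is independently reproducible.  Kept
#' below 2^31 - 1.
#' @param seed integer root seed
#' @param stage stage name (hashed into the derivation)
#' @return integer seed
#' @export
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h * 1103 + 12345) %% 2147483647)
}

## reverse complement for plain character 4-mers (ACGT alphabet)
revcompMotif <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    vapply(strsplit(x, ""), function(b)
        paste(rev(unname(comp[b])), collapse = ""), character(1))
}

## evaluate expr under a temporary RNG seed, restoring global state
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## Dirichlet draw via normalised gammas; alpha a positive vector
rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) { # numeric underflow guard for tiny alphas
        g[which.max(alpha)] <- 1
    }
    g / sum(g)
}
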