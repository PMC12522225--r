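#' Profiler configuration
#'
#' Filtering and orientation settings for [extractEndMotifs()].  The
#' default end convention counts the 5' terminal 4-mer of each strand --
#' the reference 4-mer at the fragment's left terminus read on the forward
#' strand, and the reverse complement of the reference 4-mer at its right
#' terminus -- so every properly-paired fragment contributes two ends.
#' `five_prime_left_only` counts only the left (forward-strand 5') motif;
#' `three_prime_both_ends` counts the 3' terminal motif of each strand,
#' which is the reverse complement of the opposite end's 5' motif.
#'
#' @param endConvention one of `"five_prime_both_ends"` (default),
#'   `"five_prime_left_only"`, `"three_prime_both_ends"`
#' @param minMappingQuality MAPQ threshold (default 30)
#' @param minFragmentLength,maxFragmentLength inclusive template-length
#'   bounds in bp (defaults 50 and 500)
#' @param minUsableFragments samples with fewer usable fragments are
#'   flagged (default 1000)
#' @return a list of class `ProfilerConfig`
#' @export
profilerConfig <- function(endConvention = c("five_prime_both_ends",
                                             "five_prime_left_only",
                                             "three_prime_both_ends"),
                           minMappingQuality = 30L,
                           minFragmentLength = 50L,
                           maxFragmentLength = 500L,
                           minUsableFragments = 1000L) {
    endConvention <- match.arg(endConvention)
    stopifnot(minFragmentLength > 0, maxFragmentLength > minFragmentLength)
    structure(list(endConvention = endConvention,
                   minMappingQuality = as.integer(minMappingQuality),
                   minFragmentLength = as.integer(minFragmentLength),
                   maxFragmentLength = as.integer(maxFragmentLength),
                   minUsableFragments = as.integer(minUsableFragments)),
              class = "ProfilerConfig")
}

## cigar soft-clip checks on the terminal operation
.startsSoftClipped <- function(cigar) grepl("^[0-9]+S", cigar)
.endsSoftClipped <- function(cigar) grepl("[0-9]+S$", cigar)

#' Extract terminal 4-mer end-motif counts from one aligned sample
#'
#' Iterates properly-paired, primary, non-duplicate fragments with
#' MAPQ >= threshold and template length within bounds; each fragment is
#' counted once (via its leftmost mate) regardless of record order.  End
#' motifs are taken from the reference sequence, not read bases, so
#' sequencing errors cannot perturb them; an end whose defining read is
#' soft-clipped at that terminus is disqualified, as is any motif window
#' containing a non-ACGT base.
#'
#' @param bamFile path to a coordinate-sorted, indexed BAM
#' @param reference path to the reference FASTA, or a named
#'   `DNAStringSet`
#' @param config a [profilerConfig()]
#' @return list with `counts` (named integer over the 256 motifs),
#'   `usable_fragments` (fragments passing all filters), and `flagged`
#'   (TRUE when below `minUsableFragments`)
#' @export
extractEndMotifs <- function(bamFile, reference,
                             config = profilerConfig()) {
    if (!file.exists(paste0(bamFile, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bamFile)))
        stop("missing BAM index for ", bamFile)
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))

    flag <- Rsamtools::scanBamFlag(
        isPaired = TRUE, isProperPair = TRUE,
        isSecondaryAlignment = FALSE, isDuplicate = FALSE,
        isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
        flag = flag, mapqFilter = config$minMappingQuality,
        what = c("qname", "rname", "pos", "cigar", "isize"))
    rec <- Rsamtools::scanBam(bamFile, param = param)[[1]]

    motifs <- enumerateMotifs(4L)
    empty <- list(counts = setNames(integer(256L), motifs),
                  usable_fragments = 0L, flagged = TRUE)
    if (length(rec$qname) == 0L) return(empty)

    left <- which(rec$isize > 0)
    right <- which(rec$isize < 0)
    keep <- abs(rec$isize[left]) >= config$minFragmentLength &
        abs(rec$isize[left]) <= config$maxFragmentLength
    left <- left[keep]
    if (length(left) == 0L) return(empty)
    rightOf <- setNames(right, rec$qname[right])
    mate <- rightOf[rec$qname[left]]

    refName <- as.character(rec$rname[left])
    fragStart <- rec$pos[left]                       # 1-based
    fragEnd <- fragStart + rec$isize[left] - 1L
    usable <- length(left)

    ## reference 4-mers at the two termini, per contig
    leftWin <- rightWin <- character(usable)
    for (ctg in unique(refName)) {
        i <- refName == ctg
        refChar <- as.character(reference[[ctg]])
        leftWin[i] <- substring(refChar, fragStart[i], fragStart[i] + 3L)
        rightWin[i] <- substring(refChar, fragEnd[i] - 3L, fragEnd[i])
    }
    ## soft-clip disqualification: left end defined by the forward
    ## (leftmost) read's start, right end by the reverse mate's end
    leftOK <- !.startsSoftClipped(rec$cigar[left])
    rightOK <- !is.na(mate) & !.endsSoftClipped(rec$cigar[mate])
    valid <- function(x) !is.na(x) & !grepl("[^ACGT]", x)

    ends <- switch(config$endConvention,
        five_prime_both_ends = c(leftWin[leftOK & valid(leftWin)],
                                 revcompMotif(rightWin[rightOK &
                                                       valid(rightWin)])),
        five_prime_left_only = leftWin[leftOK & valid(leftWin)],
        three_prime_both_ends = c(rightWin[rightOK & valid(rightWin)],
                                  revcompMotif(leftWin[leftOK &
                                                       valid(leftWin)])))
    counts <- tabulate(factor(ends, levels = motifs), 256L)
    names(counts) <- motifs
    list(counts = counts, usable_fragments = usable,
         flagged = usable < config$minUsableFragments)
}

#' Profile a set of aligned samples into a MotifExperiment
#'
#' Runs [extractEndMotifs()] over each sample's BAM and assembles the
#' count rows into a [MotifExperiment-class]; `colData` records
#' `usable_fragments` and the low-coverage flag.
#'
#' @param bamFiles named character vector of BAM paths (names = sample ids)
#' @param reference FASTA path or `DNAStringSet`
#' @param config a [profilerConfig()]
#' @param colData optional per-sample metadata joined into the result
#' @return a [MotifExperiment-class]
#' @export
profileSamples <- function(bamFiles, reference, config = profilerConfig(),
                           colData = NULL) {
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    rows <- lapply(bamFiles, extractEndMotifs, reference = reference,
                   config = config)
    counts <- vapply(rows, `[[`, numeric(256L), "counts")
    colnames(counts) <- names(bamFiles)
    me <- MotifExperiment(counts, colData = colData)
    me$profiled_fragments <- vapply(rows, `[[`, numeric(1),
                                    "usable_fragments")
    me$low_coverage <- vapply(rows, `[[`, logical(1), "flagged")
    me
}
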