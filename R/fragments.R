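## Round-trip fixture machinery: synthesise a toy reference plus sorted,
## indexed paired-end alignments whose terminal 4-mers reproduce a given
## end-motif count matrix under the profiler's default both-ends 5'
## convention, with bookkeeping ground truth written alongside.

.FRAG_LEN <- 60L   # synthetic fragment length (within default 50-500 bounds)
.READ_LEN <- 30L
.SEG_SPACE <- 64L  # reference bases reserved per unique motif pair

#' Write synthetic paired-end fragments matching an end-motif count matrix
#'
#' Builds a toy single-contig reference in which every required (left,
#' right) end-motif pair occupies a dedicated 60 bp segment, then emits,
#' per sample, a coordinate-sorted and indexed BAM of properly-paired
#' 30 bp reads whose fragments reproduce the requested end-motif counts
#' under the default profiling convention (5' terminal 4-mer of each
#' strand, both ends counted).  Because both fragment ends are counted,
#' each row of `counts` is laid out onto `ceiling(rowSum / 2)` fragments;
#' when a row sum is odd the last motif is placed twice and the extra
#' occurrence is reflected in the bookkeeping.  The bookkeeping counts --
#' what was actually placed -- are the ground truth the profiler must
#' reproduce exactly.
#'
#' @param cohort cohort metadata (`sample_id` column); rows must match
#'   `counts` samples
#' @param counts a [MotifExperiment-class] or motifs x samples count matrix
#' @param dir output directory (created if needed)
#' @param referenceLength reference contig length in bp; must be large
#'   enough to place every distinct motif pair (error otherwise)
#' @return list with elements `bam` (named vector of BAM paths),
#'   `reference` (FASTA path), `truth` (motifs x samples bookkeeping count
#'   matrix) and `truthFile` (JSON path)
#' @export
writeFragments <- function(cohort, counts, dir,
                           referenceLength = NULL) {
    cnt <- if (is(counts, "MotifExperiment")) motifCounts(counts)
           else as.matrix(counts)
    stopifnot(identical(rownames(cnt), enumerateMotifs(4L)),
              ncol(cnt) == nrow(cohort))
    colnames(cnt) <- cohort$sample_id
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    motifs <- enumerateMotifs(4L)

    ## per sample: expand counts to an end-motif sequence, pair consecutive
    ## ends into fragments (left, right); odd totals duplicate the last end
    pairsBySample <- lapply(colnames(cnt), function(sid) {
        ends <- rep(motifs, cnt[, sid])
        if (length(ends) == 0L)
            return(data.frame(left = character(0), right = character(0)))
        if (length(ends) %% 2L == 1L) ends <- c(ends, ends[length(ends)])
        data.frame(left = ends[c(TRUE, FALSE)], right = ends[c(FALSE, TRUE)],
                   stringsAsFactors = FALSE)
    })
    names(pairsBySample) <- colnames(cnt)

    allPairs <- unique(do.call(rbind, pairsBySample))
    nSeg <- nrow(allPairs)
    needed <- max(nSeg, 1L) * .SEG_SPACE
    if (is.null(referenceLength)) referenceLength <- needed
    if (referenceLength < needed)
        stop("reference too short: need ", needed, " bp to place ",
             nSeg, " motif pairs, got ", referenceLength)

    ## reference segment for pair (a, b): a + filler + revcomp(b), so the
    ## left reference 4-mer is a and the 5' motif of the right (reverse
    ## strand) end is b
    filler <- paste(rep("ACGT", .FRAG_LEN / 4), collapse = "")
    segs <- character(nSeg)
    if (nSeg)
        segs <- paste0(allPairs$left,
                       substr(filler, 1L, .FRAG_LEN - 8L),
                       revcompMotif(allPairs$right))
    pad <- paste(rep("A", .SEG_SPACE - .FRAG_LEN), collapse = "")
    refSeq <- paste0(paste0(segs, pad, collapse = ""),
                     paste(rep("A", referenceLength - nSeg * .SEG_SPACE),
                           collapse = ""))
    ref <- Biostrings::DNAStringSet(refSeq)
    names(ref) <- "chrS"
    refFile <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(ref, refFile)
    Rsamtools::indexFa(refFile)

    segOf <- function(df) # 0-based segment offsets for each fragment
        (match(paste(df$left, df$right),
               paste(allPairs$left, allPairs$right)) - 1L) * .SEG_SPACE

    header <- c("@HD\tVN:1.6",
                paste0("@SQ\tSN:chrS\tLN:", referenceLength))
    refChar <- refSeq
    bamPaths <- vapply(colnames(cnt), function(sid) {
        df <- pairsBySample[[sid]]
        sam <- file.path(dir, paste0(sid, ".sam"))
        lines <- header
        if (nrow(df)) {
            o <- segOf(df)
            qn <- sprintf("%s_f%06d", sid, seq_len(nrow(df)))
            p1 <- o + 1L
            p2 <- o + .FRAG_LEN - .READ_LEN + 1L
            s1 <- substring(refChar, p1, p1 + .READ_LEN - 1L)
            s2 <- substring(refChar, p2, p2 + .READ_LEN - 1L)
            qual <- paste(rep("I", .READ_LEN), collapse = "")
            cig <- paste0(.READ_LEN, "M")
            r1 <- paste(qn, 99L, "chrS", p1, 60L, cig, "=", p2, .FRAG_LEN,
                        s1, qual, sep = "\t")
            r2 <- paste(qn, 147L, "chrS", p2, 60L, cig, "=", p1, -.FRAG_LEN,
                        s2, qual, sep = "\t")
            ord <- order(c(p1, p2))
            lines <- c(lines, c(r1, r2)[ord])
        }
        writeLines(lines, sam)
        bam <- Rsamtools::asBam(sam, file.path(dir, sid), overwrite = TRUE,
                                indexDestination = TRUE)
        unlink(sam)
        bam
    }, character(1))

    truth <- vapply(colnames(cnt), function(sid) {
        df <- pairsBySample[[sid]]
        tabulate(factor(c(df$left, df$right), levels = motifs), 256L)
    }, numeric(256L))
    rownames(truth) <- motifs

    truthFile <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
        list(convention = "five_prime_both_ends",
             fragment_length = .FRAG_LEN,
             counts = as.data.frame(t(truth))),
        truthFile, digits = NA)
    list(bam = bamPaths, reference = refFile, truth = truth,
         truthFile = truthFile)
}
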