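#' Test pairs of placed positions for the tail-to-tail configuration
#'
#' Two placed end reads of one clone are tail-to-tail when they reproduce
#' the geometry of the clone in its source genome: both on the same
#' target sequence, on opposite strands, facing inward (the plus-strand
#' read strictly to the left of the minus-strand read, 3' ends pointing
#' toward each other), and with an outer span — the implied insert size,
#' `max(end) - min(start) + 1` — no larger than `maxSeparation`.
#' Positions with identical start coordinates are conservatively rejected
#' (a degenerate overlap is not a credible insert).
#'
#' @param posA,posB parallel `GRanges` of equal length; element `i` of
#'   each is one candidate pair.
#' @param maxSeparation maximum outer span in bases (default 200000, a
#'   BAC-insert-scale cap).
#' @return logical vector, `TRUE` where the pair is tail-to-tail.
#' @examples
#' a <- GenomicRanges::GRanges("chr1:1001-1600:+")
#' b <- GenomicRanges::GRanges("chr1:150001-150600:-")
#' isTailToTail(a, b)  # TRUE
#' @export
isTailToTail <- function(posA, posB, maxSeparation = 200000) {
    stopifnot(is(posA, "GRanges"), is(posB, "GRanges"),
              length(posA) == length(posB))
    sA <- as.character(BiocGenerics::strand(posA))
    sB <- as.character(BiocGenerics::strand(posB))
    stranded <- sA %in% c("+", "-") & sB %in% c("+", "-")
    sameTarget <- as.character(GenomeInfoDb::seqnames(posA)) ==
        as.character(GenomeInfoDb::seqnames(posB))
    opposite <- stranded & sA != sB
    startPlus <- ifelse(sA == "+", BiocGenerics::start(posA),
                        BiocGenerics::start(posB))
    startMinus <- ifelse(sA == "-", BiocGenerics::start(posA),
                         BiocGenerics::start(posB))
    span <- pmax(BiocGenerics::end(posA), BiocGenerics::end(posB)) -
        pmin(BiocGenerics::start(posA), BiocGenerics::start(posB)) + 1
    sameTarget & opposite & startPlus < startMinus &
        span <= maxSeparation
}

#' Outer span of a candidate pair
#' @inheritParams isTailToTail
#' @return integer vector of implied insert sizes in bases.
#' @export
pairSeparation <- function(posA, posB) {
    pmax(BiocGenerics::end(posA), BiocGenerics::end(posB)) -
        pmin(BiocGenerics::start(posA), BiocGenerics::start(posB)) + 1
}

#' Classify every clone as tail-to-tail, unpaired or incomplete
#'
#' Applies the pair criterion of [isTailToTail()] clone by clone. A clone
#' with fewer than two positioned ends is `incomplete`. Otherwise every
#' combination of the two ends' retained (possibly tied) positions is
#' examined: if any combination is tail-to-tail the clone is
#' `tail_to_tail`, with the passing combination of smallest separation
#' reported as witness; if none is, the clone is `positioned_not_paired`
#' and both its reads count as unpaired.
#'
#' @param placements a `GRanges` from [selectPlacements()].
#' @param registry a [PairRegistry-class] covering the reads.
#' @param maxSeparation maximum outer span in bases.
#' @return a `data.frame` with one row per clone in the registry:
#'   `cloneId`, `category` (factor: `tail_to_tail`,
#'   `positioned_not_paired`, `incomplete`), and witness columns
#'   `targetId`, `startA`, `endA`, `strandA`, `startB`, `endB`, `strandB`,
#'   `separation` (`NA` unless tail-to-tail; A is the forward-role end).
#' @export
classifyClones <- function(placements, registry, maxSeparation = 200000) {
    stopifnot(is(placements, "GRanges"), is(registry, "PairRegistry"))
    reg <- data.table::as.data.table(as.data.frame(registry@reads))
    pl <- data.table::data.table(
        readId = S4Vectors::mcols(placements)$readId,
        targetId = as.character(GenomeInfoDb::seqnames(placements)),
        start = BiocGenerics::start(placements),
        end = BiocGenerics::end(placements),
        strand = as.character(BiocGenerics::strand(placements)))
    unknown <- setdiff(pl$readId, reg$readId)
    if (length(unknown))
        stop("placed read(s) absent from the registry: ",
             paste(utils::head(unknown, 3L), collapse = ", "),
             call. = FALSE)
    pp <- merge(pl, reg, by = "readId", allow.cartesian = TRUE)
    fwd <- pp[pp$role == "forward_end", ]
    rev <- pp[pp$role == "reverse_end", ]
    both <- merge(fwd, rev, by = "cloneId", suffixes = c("A", "B"),
                  allow.cartesian = TRUE)
    verdicts <- data.frame(
        cloneId = cloneIds(registry),
        category = factor("incomplete",
            levels = c("tail_to_tail", "positioned_not_paired",
                       "incomplete")),
        targetId = NA_character_,
        startA = NA_integer_, endA = NA_integer_,
        strandA = NA_character_,
        startB = NA_integer_, endB = NA_integer_,
        strandB = NA_character_,
        separation = NA_integer_,
        stringsAsFactors = FALSE)
    if (nrow(both)) {
        grA <- GenomicRanges::GRanges(both$targetIdA,
            IRanges::IRanges(both$startA, both$endA), both$strandA)
        grB <- GenomicRanges::GRanges(both$targetIdB,
            IRanges::IRanges(both$startB, both$endB), both$strandB)
        both$pass <- isTailToTail(grA, grB, maxSeparation)
        both$sep <- pairSeparation(grA, grB)
        idx <- match(both$cloneId, verdicts$cloneId)
        verdicts$category[unique(idx)] <- "positioned_not_paired"
        hit <- both[both$pass, ]
        if (nrow(hit)) {
            hit <- hit[order(hit$sep), ]
            hit <- hit[!duplicated(hit$cloneId), ]
            i <- match(hit$cloneId, verdicts$cloneId)
            verdicts$category[i] <- "tail_to_tail"
            verdicts$targetId[i] <- hit$targetIdA
            verdicts$startA[i] <- hit$startA
            verdicts$endA[i] <- hit$endA
            verdicts$strandA[i] <- hit$strandA
            verdicts$startB[i] <- hit$startB
            verdicts$endB[i] <- hit$endB
            verdicts$strandB[i] <- hit$strandB
            verdicts$separation[i] <- hit$sep
        }
    }
    verdicts
}

#' Write per-clone verdicts as TSV
#'
#' @param verdicts result of [classifyClones()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVerdicts <- function(verdicts, path) {
    utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
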