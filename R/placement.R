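#' Reduce hits to top-score placements under an optional score cutoff
#'
#' For each read, hits scoring below `scoreCutoff` are discarded first
#' (the cutoff is inclusive: a hit at exactly the cutoff survives), then
#' the highest remaining score is found and every position achieving it
#' is retained — a tie keeps all tied locations, so that pair
#' classification can check each of them. Positions identical in
#' (target, start, end, strand) are deduplicated. Reads with no surviving
#' hit are simply absent from the result.
#'
#' @param hits a `GRanges` of hits with metadata columns `readId` and
#'   `score` (see [readBlastHits()]).
#' @param scoreCutoff numeric score threshold, or `NULL` for no filtering
#'   (equivalent to `-Inf`).
#' @return a `GRanges` of retained placements, one range per retained
#'   position, with metadata columns `readId` and `score` (the read's top
#'   score). `metadata()$scoreCutoff` records the cutoff applied.
#' @examples
#' gr <- GenomicRanges::GRanges(c("chr1:100-159:+", "chr2:5-64:+"),
#'                              readId = "r1", score = c(50, 60))
#' selectPlacements(gr)             # the score-60 hit only
#' selectPlacements(gr, scoreCutoff = 65)  # empty: read unpositioned
#' @export
selectPlacements <- function(hits, scoreCutoff = NULL) {
    stopifnot(is(hits, "GRanges"))
    mc <- S4Vectors::mcols(hits)
    if (!all(c("readId", "score") %in% colnames(mc)))
        stop("hits need metadata columns 'readId' and 'score'",
             call. = FALSE)
    if (is.null(scoreCutoff)) scoreCutoff <- -Inf
    hits <- hits[mc$score >= scoreCutoff]
    if (length(hits)) {
        top <- stats::ave(S4Vectors::mcols(hits)$score,
                          S4Vectors::mcols(hits)$readId, FUN = max)
        hits <- hits[S4Vectors::mcols(hits)$score == top]
        key <- paste(S4Vectors::mcols(hits)$readId,
                     GenomeInfoDb::seqnames(hits),
                     BiocGenerics::start(hits), BiocGenerics::end(hits),
                     BiocGenerics::strand(hits))
        hits <- hits[!duplicated(key)]
    }
    out <- hits[, c("readId", "score")]
    S4Vectors::metadata(out)$scoreCutoff <- scoreCutoff
    out
}

#' Read ids positioned in a placement set
#'
#' @param placements a `GRanges` from [selectPlacements()].
#' @return character vector of distinct positioned read ids.
#' @export
positionedReads <- function(placements) {
    unique(S4Vectors::mcols(placements)$readId)
}
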