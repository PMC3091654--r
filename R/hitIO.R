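.BLAST12 <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

#' Describe a BLAST-style tabular dialect
#'
#' The default layout is the stock 12-column BLAST tabular format. When a
#' 13th `score` column is declared (`rawScore = TRUE`) it becomes the
#' score used downstream; otherwise `bitscore` is used. Any column may be
#' designated the score via `scoreColumn`, e.g. for aligners whose raw
#' alignment score occupies a custom position.
#'
#' @param columns ordered character vector of column names.
#' @param rawScore logical; append a trailing raw `score` column to the
#'   stock layout and use it as the score.
#' @param scoreColumn explicit score column name; overrides `rawScore`.
#' @return a [BlastTabularDialect-class].
#' @examples
#' blastDialect()                 # 12 columns, score = bitscore
#' blastDialect(rawScore = TRUE)  # 13 columns, score = raw score
#' @export
blastDialect <- function(columns = NULL, rawScore = FALSE,
                         scoreColumn = NULL) {
    if (is.null(columns))
        columns <- if (rawScore) c(.BLAST12, "score") else .BLAST12
    if (is.null(scoreColumn))
        scoreColumn <- if ("score" %in% columns) "score" else "bitscore"
    new("BlastTabularDialect", columns = columns,
        scoreColumn = scoreColumn)
}

setMethod("show", "BlastTabularDialect", function(object) {
    cat(sprintf(
        "BlastTabularDialect: %d columns, score column '%s'\n",
        length(object@columns), object@scoreColumn))
})

#' Read alignment hits into a GRanges
#'
#' Parses a BLAST-style tabular hit file into a [GenomicRanges::GRanges]
#' with one range per hit: `seqnames` is the framework-genome target,
#' coordinates are 1-based closed, and strand is made explicit from the
#' subject coordinate order (`sstart > send` means the minus strand),
#' never left encoded in the coordinates themselves. Metadata columns
#' carry `readId`, the dialect-selected `score`, and every remaining input
#' column so that [writeBlastHits()] round-trips losslessly.
#'
#' Every hit is retained: best-hit selection and tie handling live in
#' [selectPlacements()], not the parser. Blank lines, trailing whitespace
#' and `#` comment lines are ignored.
#'
#' @param file path to the hit table (or a connection).
#' @param dialect a [BlastTabularDialect-class]; see [blastDialect()].
#' @return a `GRanges`, empty for an empty file.
#' @examples
#' f <- tempfile()
#' writeLines(paste("r1", "chr1", 98.3, 60, 1, 0, 1, 60, 100, 159,
#'                  1e-20, 111, sep = "\t"), f)
#' readBlastHits(f)
#' @export
readBlastHits <- function(file, dialect = blastDialect()) {
    lines <- readLines(file)
    parseBlastHits(lines, dialect)
}

#' @rdname readBlastHits
#' @param lines character vector, one element per input line.
#' @export
parseBlastHits <- function(lines, dialect = blastDialect()) {
    stopifnot(is(dialect, "BlastTabularDialect"))
    cols <- dialect@columns
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) return(.emptyHits())
    fields <- strsplit(trimws(lines[keep], which = "right"), "\t",
                       fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != length(cols))) {
        i <- which(nf != length(cols))[1L]
        stop(sprintf("line %d: expected %d columns, found %d",
                     keep[i], length(cols), nf[i]), call. = FALSE)
    }
    mat <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE,
                  dimnames = list(NULL, cols))
    num <- function(col) {
        v <- suppressWarnings(as.numeric(mat[, col]))
        if (anyNA(v)) {
            i <- which(is.na(v))[1L]
            stop(sprintf("line %d: non-numeric value '%s' in column %s",
                         keep[i], mat[i, col], col), call. = FALSE)
        }
        v
    }
    sstart <- num("sstart"); send <- num("send")
    score <- num(dialect@scoreColumn)
    if (any(!is.finite(score)))
        stop("non-finite alignment score encountered", call. = FALSE)
    minus <- sstart > send
    gr <- GenomicRanges::GRanges(
        seqnames = mat[, "sseqid"],
        ranges = IRanges::IRanges(start = pmin(sstart, send),
                                  end = pmax(sstart, send)),
        strand = ifelse(minus, "-", "+"),
        readId = mat[, "qseqid"],
        score = score)
    aux <- setdiff(cols, c("qseqid", "sseqid", "sstart", "send",
                           dialect@scoreColumn))
    for (col in aux)
        S4Vectors::mcols(gr)[[col]] <- mat[, col]
    gr
}

.emptyHits <- function() {
    GenomicRanges::GRanges(readId = character(), score = numeric())
}

#' Write hits back to BLAST-style tabular text
#'
#' Inverse of [readBlastHits()]: minus-strand hits are emitted with
#' `sstart > send`, plus-strand hits with `sstart < send`. Auxiliary
#' metadata columns fill their dialect positions; dialect columns absent
#' from the hits are written as `NA`.
#'
#' @param hits a `GRanges` as produced by [readBlastHits()] or
#'   [simulateDataset()].
#' @param file output path, or `NULL` to return the lines.
#' @param dialect a [BlastTabularDialect-class].
#' @return the output lines, invisibly when `file` is given.
#' @export
writeBlastHits <- function(hits, file = NULL, dialect = blastDialect()) {
    stopifnot(is(hits, "GRanges"), is(dialect, "BlastTabularDialect"))
    cols <- dialect@columns
    minus <- as.character(BiocGenerics::strand(hits)) == "-"
    mc <- S4Vectors::mcols(hits)
    out <- matrix(NA_character_, nrow = length(hits), ncol = length(cols),
                  dimnames = list(NULL, cols))
    out[, "qseqid"] <- as.character(mc$readId)
    out[, "sseqid"] <- as.character(GenomeInfoDb::seqnames(hits))
    out[, "sstart"] <- as.character(
        ifelse(minus, BiocGenerics::end(hits), BiocGenerics::start(hits)))
    out[, "send"] <- as.character(
        ifelse(minus, BiocGenerics::start(hits), BiocGenerics::end(hits)))
    out[, dialect@scoreColumn] <- .formatNum(mc$score)
    aux <- setdiff(cols, c("qseqid", "sseqid", "sstart", "send",
                           dialect@scoreColumn))
    for (col in aux)
        if (col %in% colnames(mc))
            out[, col] <- as.character(mc[[col]])
    lines <- if (nrow(out)) apply(out, 1L, paste, collapse = "\t")
             else character()
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    invisible(lines)
}

.formatNum <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           as.character(x))
}
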