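#' Build a PairRegistry from read names
#'
#' Parses each read id with a regular expression whose first capture group
#' is the clone id and whose second is the end code, then maps end codes
#' to roles. The default rule matches the common `<clone>.F` / `<clone>.R`
#' (or `_F` / `_R`, case-insensitive) convention for BAC-end reads.
#'
#' Clones with a single parseable end are retained: they contribute to the
#' positioned-read count but can never form a pair. Under `strict = TRUE`
#' (the default) an unparseable id or an end code missing from `endCodes`
#' is an error; under lenient parsing such reads are dropped and listed in
#' `skippedReads()` so that silent pairing bugs cannot hide.
#'
#' @param readIds character vector of read identifiers.
#' @param pattern regular expression with exactly two capture groups:
#'   clone id, then end code.
#' @param endCodes named character vector mapping captured end codes to
#'   `"forward_end"` / `"reverse_end"`.
#' @param strict logical; error on unparseable ids (default) or skip them.
#' @return a [PairRegistry-class].
#' @examples
#' registryFromNames(c("C1.F", "C1.R", "C2.F"))
#' @export
registryFromNames <- function(readIds,
                              pattern = "^(.+)[._]([FRfr])$",
                              endCodes = c(F = "forward_end",
                                           R = "reverse_end",
                                           f = "forward_end",
                                           r = "reverse_end"),
                              strict = TRUE) {
    readIds <- as.character(readIds)
    m <- regmatches(readIds, regexec(pattern, readIds))
    parsed <- lengths(m) == 3L
    code <- ifelse(parsed, vapply(m, function(g) g[3L][1L], ""), NA)
    known <- parsed & code %in% names(endCodes)
    if (strict && !all(known)) {
        bad <- readIds[!known][1L]
        stop("cannot derive (clone, end) from read id '", bad,
             "' with the supplied naming rule", call. = FALSE)
    }
    clone <- vapply(m[known], `[`, "", 2L)
    role <- unname(endCodes[code[known]])
    .newRegistry(readIds[known], clone, role, skipped = readIds[!known])
}

#' Build a PairRegistry from an explicit pairing table
#'
#' @param pairing a data.frame (or coercible) with columns `read_id`,
#'   `clone_id` and `end`; `end` is translated through `endCodes`.
#' @param endCodes named character vector mapping end codes to roles; the
#'   default accepts `F`/`R` (any case), `forward`/`reverse` and the full
#'   role names.
#' @param strict logical; error on unknown end codes (default) or skip.
#' @return a [PairRegistry-class].
#' @examples
#' registryFromTable(data.frame(read_id = c("a", "b"),
#'                              clone_id = c("C1", "C1"),
#'                              end = c("f", "r")))
#' @export
registryFromTable <- function(pairing,
                              endCodes = c(F = "forward_end",
                                           R = "reverse_end",
                                           f = "forward_end",
                                           r = "reverse_end",
                                           forward = "forward_end",
                                           reverse = "reverse_end",
                                           forward_end = "forward_end",
                                           reverse_end = "reverse_end"),
                              strict = TRUE) {
    pairing <- as.data.frame(pairing)
    need <- c("read_id", "clone_id", "end")
    if (!all(need %in% colnames(pairing)))
        stop("pairing table needs columns ",
             paste(need, collapse = ", "), call. = FALSE)
    code <- as.character(pairing$end)
    known <- code %in% names(endCodes)
    if (strict && !all(known))
        stop("unknown end code '", code[!known][1L], "' for read '",
             pairing$read_id[!known][1L], "'", call. = FALSE)
    .newRegistry(as.character(pairing$read_id)[known],
                 as.character(pairing$clone_id)[known],
                 unname(endCodes[code[known]]),
                 skipped = as.character(pairing$read_id)[!known])
}

.newRegistry <- function(readId, cloneId, role, skipped = character()) {
    df <- S4Vectors::DataFrame(readId = readId, cloneId = cloneId,
                               role = role)
    df <- df[order(df$cloneId, df$role, df$readId), , drop = FALSE]
    rownames(df) <- NULL
    new("PairRegistry", reads = df, skipped = skipped)
}

#' Read or write a pairing file
#'
#' The pairing file is a headered, UTF-8 TSV with columns `read_id`,
#' `clone_id` and `end`; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param registry a [PairRegistry-class] (for writing).
#' @param ... passed on to [registryFromTable()].
#' @return `readPairingFile()` returns a [PairRegistry-class];
#'   `writePairingFile()` returns `path` invisibly.
#' @export
readPairingFile <- function(path, ...) {
    if (!file.exists(path))
        stop("pairing file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = "character")
    registryFromTable(df, ...)
}

#' @rdname readPairingFile
#' @export
writePairingFile <- function(registry, path) {
    stopifnot(is(registry, "PairRegistry"))
    df <- as.data.frame(registry)
    names(df) <- c("read_id", "clone_id", "end")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @describeIn registry-accessors number of reads registered (`t`).
#' @export
setMethod("totalReads", "PairRegistry", function(x) nrow(x@reads))

#' @describeIn registry-accessors number of distinct clones.
#' @export
setMethod("totalClones", "PairRegistry",
    function(x) length(unique(x@reads$cloneId)))

#' @describeIn registry-accessors clones with both end roles present.
#' @export
setMethod("completePairs", "PairRegistry", function(x) {
    sum(table(unique(data.frame(clone = x@reads$cloneId,
                                role = x@reads$role))$clone) == 2L)
})

#' @describeIn registry-accessors read identifiers, ordered by clone.
#' @export
setMethod("readIds", "PairRegistry", function(x) x@reads$readId)

#' @describeIn registry-accessors distinct clone identifiers.
#' @export
setMethod("cloneIds", "PairRegistry",
    function(x) unique(x@reads$cloneId))

#' Reads excluded during lenient registry construction
#' @param x a [PairRegistry-class].
#' @return character vector of skipped read ids.
#' @export
skippedReads <- function(x) {
    stopifnot(is(x, "PairRegistry"))
    x@skipped
}

#' @export
#' @describeIn registryFromTable coerce a registry back to the
#'   (readId, cloneId, role) table.
setMethod("as.data.frame", "PairRegistry",
    function(x, row.names = NULL, optional = FALSE, ...)
        as.data.frame(x@reads))

setMethod("show", "PairRegistry", function(object) {
    cat(sprintf(
        "PairRegistry: %d reads, %d clones (%d complete pairs)\n",
        totalReads(object), totalClones(object), completePairs(object)))
    if (length(object@skipped))
        cat(sprintf("  %d read ids skipped during parsing\n",
                    length(object@skipped)))
})
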