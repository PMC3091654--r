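#' @import methods
NULL

.END_ROLES <- c("forward_end", "reverse_end")

#' PairRegistry: which reads pair into which clones
#'
#' A `PairRegistry` records, for every read in a paired-end data set, the
#' clone (e.g. a BAC) it was sequenced from and which end of the clone it
#' represents. Clones with only one sequenced end are kept: they can be
#' positioned on a framework genome but can never form a tail-to-tail pair,
#' and they stay in the total-read denominator `t` used by every
#' percentage downstream.
#'
#' @slot reads a [S4Vectors::DataFrame] with columns `readId`, `cloneId`
#'   and `role` (one of `"forward_end"`, `"reverse_end"`).
#' @slot skipped character vector of read ids excluded during lenient
#'   parsing (empty under strict parsing).
#'
#' @seealso [registryFromNames()], [registryFromTable()],
#'   [readPairingFile()]
#' @export
setClass("PairRegistry",
    slots = c(reads = "DataFrame", skipped = "character"))

setValidity("PairRegistry", function(object) {
    df <- object@reads
    need <- c("readId", "cloneId", "role")
    if (!all(need %in% colnames(df)))
        return(sprintf("reads must have columns %s",
                       paste(need, collapse = ", ")))
    if (!all(df$role %in% .END_ROLES))
        return("role must be 'forward_end' or 'reverse_end'")
    if (anyDuplicated(df$readId))
        return(sprintf("duplicate read id: %s",
                       df$readId[duplicated(df$readId)][1L]))
    key <- paste(df$cloneId, df$role, sep = "\r")
    if (anyDuplicated(key)) {
        i <- which(key == key[duplicated(key)][1L])
        return(sprintf(
            "clone '%s' has two reads for role '%s': '%s' and '%s'",
            df$cloneId[i[1L]], df$role[i[1L]],
            df$readId[i[1L]], df$readId[i[2L]]))
    }
    TRUE
})

#' BlastTabularDialect: layout of an alignment hit table
#'
#' Describes a BLAST-style tabular hit file: the ordered column names and
#' which column carries the alignment score that all downstream filtering
#' uses. The stock 12-column layout (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`) and a 13-column
#' variant with a trailing raw `score` column are both expressible.
#'
#' @slot columns ordered character vector of column names; must contain
#'   `qseqid`, `sseqid`, `sstart` and `send`.
#' @slot scoreColumn name of the column used as the alignment score.
#'
#' @seealso [blastDialect()], [readBlastHits()]
#' @export
setClass("BlastTabularDialect",
    slots = c(columns = "character", scoreColumn = "character"))

setValidity("BlastTabularDialect", function(object) {
    need <- c("qseqid", "sseqid", "sstart", "send")
    if (!all(need %in% object@columns))
        return(sprintf("columns must include %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(object@columns))
        return("duplicate column names")
    if (length(object@scoreColumn) != 1L ||
        !object@scoreColumn %in% object@columns)
        return("scoreColumn must name exactly one of the columns")
    TRUE
})

#' SimConfig: parameters of the paired-end placement simulator
#'
#' Holds the geometry of the synthetic framework genome, the clone insert
#' model, the per-read positioning behaviour and the score model used by
#' [simulateDataset()]. See that function for the generative process.
#'
#' @slot nChromosomes number of chromosomes in the synthetic genome.
#' @slot chromosomeLength length of each chromosome, bases.
#' @slot nClones number of clones; each contributes two end reads.
#' @slot insertSizeMean,insertSizeSd normal insert-size model, bases.
#' @slot insertSizeMin,insertSizeMax truncation bounds for insert sizes.
#' @slot readLength length of each simulated end read, bases.
#' @slot pPosition probability a read receives any placement at all.
#' @slot pCorrect probability a positioned read is placed at its true
#'   location (otherwise a uniform random location and strand).
#' @slot scoreTrueLocation,scoreFalseLocation integer modes of the score
#'   distributions for correct and spurious best hits.
#' @slot scoreScale mean absolute deviation of the geometric score tails.
#' @slot nDecoyHits mean number of extra, strictly lower-scoring decoy
#'   hits added per positioned read (Poisson).
#' @slot seed integer RNG seed; identical configs give identical output.
#'
#' @seealso [simConfig()], [simulateDataset()], [expectedRates()]
#' @export
setClass("SimConfig",
    slots = c(
        nChromosomes = "integer", chromosomeLength = "numeric",
        nClones = "integer",
        insertSizeMean = "numeric", insertSizeSd = "numeric",
        insertSizeMin = "numeric", insertSizeMax = "numeric",
        readLength = "integer",
        pPosition = "numeric", pCorrect = "numeric",
        scoreTrueLocation = "numeric", scoreFalseLocation = "numeric",
        scoreScale = "numeric", nDecoyHits = "numeric",
        seed = "integer"))

setValidity("SimConfig", function(object) {
    p <- c(object@pPosition, object@pCorrect)
    if (any(p < 0 | p > 1))
        return("pPosition and pCorrect must lie in [0, 1]")
    if (object@insertSizeMin > object@insertSizeMax)
        return("insertSizeMin must not exceed insertSizeMax")
    if (object@insertSizeMean + 4 * object@insertSizeSd >=
        object@chromosomeLength)
        return("insert sizes incompatible with chromosome length")
    if (object@insertSizeMax >= object@chromosomeLength)
        return("insertSizeMax must be smaller than chromosomeLength")
    if (2 * object@readLength >= object@insertSizeMin)
        return("insertSizeMin must exceed twice the read length")
    if (object@scoreTrueLocation < 1 || object@scoreFalseLocation < 1 ||
        object@scoreScale <= 0)
        return("score distribution parameters must be positive")
    if (object@nDecoyHits < 0)
        return("nDecoyHits must be non-negative")
    if (object@nClones < 1 || object@nChromosomes < 1)
        return("need at least one clone and one chromosome")
    TRUE
})

#' MetricsSummary: one evaluation's headline counts and percentages
#'
#' Summary of one (aligner, parameter set, cutoff) evaluation: `X`
#' positioned reads out of `t` total, `o` reads belonging to tail-to-tail
#' clones (two per such clone), and the clone-level counts. Percentage
#' accessors derive the read-denominated and clone-denominated figures.
#'
#' @slot X number of positioned reads.
#' @slot t total number of reads in the registry.
#' @slot o number of reads in tail-to-tail clones (always even).
#' @slot nClones total number of clones in the registry.
#' @slot nTailToTail number of clones classified tail-to-tail.
#'
#' @seealso [summarizeVerdicts()], [pctPositioned()]
#' @export
setClass("MetricsSummary",
    slots = c(X = "integer", t = "integer", o = "integer",
              nClones = "integer", nTailToTail = "integer"))

setValidity("MetricsSummary", function(object) {
    if (object@t < 0 || object@X < 0 || object@o < 0)
        return("counts must be non-negative")
    if (object@X > object@t) return("X cannot exceed t")
    if (object@o > object@X) return("o cannot exceed X")
    if (object@o %% 2L != 0L) return("o must be even (two reads per pair)")
    if (object@nTailToTail > object@nClones)
        return("tail-to-tail clones cannot exceed total clones")
    TRUE
})
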