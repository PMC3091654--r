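#' Theoretical maximum number of reads in correct pairs
#'
#' Under the assumption that every positioned read is positioned
#' correctly and that positioning the two ends of a clone are independent
#' events, the expected number of reads falling in correctly-paired
#' clones is `e = X^2 / t`: each end is positioned with probability
#' `X / t`, a clone pairs with probability `(X / t)^2`, and each paired
#' clone contributes two reads. In percentage coordinates this is the
#' curve `y = x^2 / 100`. Observed counts may exceed it slightly when the
#' two ends' positioning is positively correlated.
#'
#' @param X number of positioned reads, `0 <= X <= t`.
#' @param t total number of reads; must be positive.
#' @return expected reads-in-pairs, a real number (never rounded).
#' @examples
#' theoreticalPairs(283315, 372046)  # ~ 215746
#' @export
theoreticalPairs <- function(X, t) {
    if (any(t <= 0)) stop("t must be positive", call. = FALSE)
    if (any(X < 0 | X > t)) stop("need 0 <= X <= t", call. = FALSE)
    X^2 / t
}

#' False positive rate of pair formation
#'
#' The shortfall of observed tail-to-tail reads `o` relative to the
#' theoretical expectation `e`: `(e - o) / e`, the proportion of
#' predicted pairings that did not materialise as tail-to-tail clones.
#' May be slightly negative when `o > e` (correlated positioning of the
#' two ends); the value is returned unclamped with a warning.
#'
#' @param o observed number of reads in tail-to-tail clones.
#' @param e expected reads-in-pairs from [theoreticalPairs()]; must be
#'   positive.
#' @return the rate, in `(-Inf, 1]`.
#' @examples
#' falsePositiveRate(130358, 230616)  # 0.43 at 2 decimals
#' @export
falsePositiveRate <- function(o, e) {
    if (any(e <= 0))
        stop("e must be positive (no pairs are predicted)",
             call. = FALSE)
    r <- (e - o) / e
    if (any(r < 0))
        warning("observed pairs exceed the theoretical maximum ",
                "(negative false positive rate)", call. = FALSE)
    r
}

#' False negative rate of positioning
#'
#' The fraction of reads for which no position was found on the
#' framework genome: `(t - X) / t`.
#'
#' @inheritParams theoreticalPairs
#' @return the rate, in `[0, 1]`.
#' @examples
#' falseNegativeRate(292916, 372046)  # 0.21 at 2 decimals
#' @export
falseNegativeRate <- function(X, t) {
    if (any(t <= 0)) stop("t must be positive", call. = FALSE)
    if (any(X < 0 | X > t)) stop("need 0 <= X <= t", call. = FALSE)
    (t - X) / t
}

#' Summarise verdicts into headline counts and percentages
#'
#' Computes `X` (positioned reads), `o` (reads in tail-to-tail clones,
#' two per clone) and the clone counts from one evaluation. The
#' tail-to-tail percentage is denominated both in total reads (as plotted
#' on trade-off curves) and in total clones (as quoted in text); both are
#' percentages of the *full* data set, never of the positioned subset
#' alone, except for the explicitly-named
#' [pctTailToTailOfPositioned()].
#'
#' @param verdicts per-clone classification from [classifyClones()].
#' @param placements the `GRanges` of retained placements the verdicts
#'   were computed from.
#' @param registry the [PairRegistry-class] defining `t`.
#' @return a [MetricsSummary-class].
#' @export
summarizeVerdicts <- function(verdicts, placements, registry) {
    stopifnot(is(registry, "PairRegistry"))
    extra <- setdiff(verdicts$cloneId, cloneIds(registry))
    if (length(extra))
        stop("verdict for clone(s) absent from the registry: ",
             paste(utils::head(extra, 3L), collapse = ", "),
             call. = FALSE)
    pos <- intersect(positionedReads(placements), readIds(registry))
    nT2T <- sum(verdicts$category == "tail_to_tail")
    new("MetricsSummary",
        X = length(pos), t = totalReads(registry), o = 2L * nT2T,
        nClones = totalClones(registry), nTailToTail = nT2T)
}

.pct <- function(num, den) if (den == 0) 0 else 100 * num / den

#' @describeIn registry-accessors percentage of reads positioned,
#'   `100 X / t`.
#' @export
setMethod("pctPositioned", "MetricsSummary",
    function(x) .pct(x@X, x@t))

#' @describeIn registry-accessors percentage of total reads in
#'   tail-to-tail clones, `100 o / t`.
#' @export
setMethod("pctTailToTailOfTotal", "MetricsSummary",
    function(x) .pct(x@o, x@t))

#' @describeIn registry-accessors percentage of positioned reads in
#'   tail-to-tail clones, `100 o / X` (0 when nothing is positioned).
#' @export
setMethod("pctTailToTailOfPositioned", "MetricsSummary",
    function(x) .pct(x@o, x@X))

#' @describeIn registry-accessors percentage of clones tail-to-tail,
#'   denominated in all clones of the data set.
#' @export
setMethod("pctClonesTailToTail", "MetricsSummary",
    function(x) .pct(x@nTailToTail, x@nClones))

#' @describeIn registry-accessors total-read denominator `t` carried by
#'   a summary.
#' @export
setMethod("totalReads", "MetricsSummary", function(x) x@t)

#' @export
#' @describeIn summarizeVerdicts one-row data.frame of all counts and
#'   percentages (full precision; rounding is display-only).
setMethod("as.data.frame", "MetricsSummary",
    function(x, row.names = NULL, optional = FALSE, ...)
        data.frame(X = x@X, t = x@t, o = x@o,
                   nClones = x@nClones, nTailToTail = x@nTailToTail,
                   pctPositioned = pctPositioned(x),
                   pctTailToTailOfTotal = pctTailToTailOfTotal(x),
                   pctTailToTailOfPositioned =
                       pctTailToTailOfPositioned(x),
                   pctClonesTailToTail = pctClonesTailToTail(x)))

setMethod("show", "MetricsSummary", function(object) {
    cat(sprintf(
        "MetricsSummary: %d/%d reads positioned (%s%%), %d in tail-to-tail clones (%s%% of total, %s%% of positioned)\n",
        object@X, object@t, roundHalfAway(pctPositioned(object), 2),
        object@o, roundHalfAway(pctTailToTailOfTotal(object), 2),
        roundHalfAway(pctTailToTailOfPositioned(object), 2)))
})

#' Round half away from zero
#'
#' Display rounding used in human-readable reports (R's [round()] rounds
#' half to even). Machine outputs always carry full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfAway(0.425, 2)  # 0.43, where round() gives 0.42
#' @export
roundHalfAway <- function(x, digits = 2) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Re-evaluate a hit set across a ladder of score cutoffs
#'
#' For every cutoff (sorted ascending) the full pipeline is re-run:
#' [selectPlacements()], [classifyClones()], [summarizeVerdicts()]; the
#' expected pair count `e` comes from [theoreticalPairs()] with the
#' registry's `t`, and the false-positive and false-negative rates from
#' the two rate functions. Raising the cutoff trades sensitivity
#' (positioned reads, fn) against specificity (fp).
#'
#' Rates are reported at full precision; round only for display. When a
#' cutoff leaves no read positioned, `e = 0` and the row's `fpRate` is
#' `NA` (no pairs are predicted, so no false-positive rate exists).
#'
#' @param hits a `GRanges` of hits (all of them, unfiltered).
#' @param registry a [PairRegistry-class].
#' @param cutoffs numeric vector of score cutoffs; at least one.
#' @param maxSeparation maximum outer span in bases for pairing.
#' @return a `data.frame` with one row per cutoff: `cutoff`, `X`, `o`,
#'   `e`, `fpRate`, `fnRate`.
#' @export
sweepCutoffs <- function(hits, registry, cutoffs,
                         maxSeparation = 200000) {
    if (!length(cutoffs)) stop("need at least one cutoff",
                               call. = FALSE)
    cutoffs <- sort(unique(as.numeric(cutoffs)))
    rows <- lapply(cutoffs, function(cut) {
        pl <- selectPlacements(hits, scoreCutoff = cut)
        v <- classifyClones(pl, registry, maxSeparation)
        s <- summarizeVerdicts(v, pl, registry)
        e <- theoreticalPairs(s@X, s@t)
        data.frame(
            cutoff = cut, X = s@X, o = s@o, e = e,
            fpRate = if (e > 0) falsePositiveRate(s@o, e) else NA_real_,
            fnRate = falseNegativeRate(s@X, s@t))
    })
    do.call(rbind, rows)
}

#' Write a cutoff sweep as TSV
#'
#' Column layout mirrors the published sweep tables: score cutoff, reads
#' with positions, reads in tail-to-tail clones, reads predicted to be in
#' tail-to-tail clones, fp rate, fn rate.
#'
#' @param sweep result of [sweepCutoffs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSweep <- function(sweep, path) {
    out <- sweep
    names(out) <- c("cutoff", "reads_with_positions",
                    "reads_in_tail_to_tail",
                    "reads_predicted_tail_to_tail",
                    "fp_rate", "fn_rate")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
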