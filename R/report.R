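#' Run one full evaluation from files on disk
#'
#' Reads a hit table and a pairing spec, applies the optional score
#' cutoff, classifies clones, and writes `<outPrefix>_summary.tsv` (one
#' row of counts and percentages) and `<outPrefix>_verdicts.tsv` (one
#' row per clone).
#'
#' @param hitsFile path to a BLAST-style tabular hit file.
#' @param pairing a [PairRegistry-class], or the path of a pairing TSV
#'   (see [readPairingFile()]).
#' @param scoreCutoff optional inclusive score cutoff.
#' @param maxSeparation maximum outer span in bases for pairing.
#' @param outPrefix path prefix for the two output files, or `NULL` to
#'   skip writing.
#' @param dialect hit-table dialect, see [blastDialect()].
#' @return a list with `summary` ([MetricsSummary-class]) and `verdicts`
#'   (data.frame), invisibly when `outPrefix` is given.
#' @export
runEvaluate <- function(hitsFile, pairing, scoreCutoff = NULL,
                        maxSeparation = 200000, outPrefix = NULL,
                        dialect = blastDialect()) {
    if (!file.exists(hitsFile))
        stop("hits file not found: ", hitsFile, call. = FALSE)
    registry <- if (is(pairing, "PairRegistry")) pairing
                else readPairingFile(pairing)
    hits <- readBlastHits(hitsFile, dialect)
    pl <- selectPlacements(hits, scoreCutoff)
    verdicts <- classifyClones(pl, registry, maxSeparation)
    s <- summarizeVerdicts(verdicts, pl, registry)
    res <- list(summary = s, verdicts = verdicts)
    if (is.null(outPrefix)) return(res)
    utils::write.table(as.data.frame(s),
                       paste0(outPrefix, "_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeVerdicts(verdicts, paste0(outPrefix, "_verdicts.tsv"))
    invisible(res)
}

#' Run a score-cutoff sweep from files on disk
#'
#' @inheritParams runEvaluate
#' @param cutoffs numeric vector of score cutoffs (at least one).
#' @return the sweep data.frame (see [sweepCutoffs()]); written to
#'   `<outPrefix>_sweep.tsv` when `outPrefix` is given.
#' @export
runSweep <- function(hitsFile, pairing, cutoffs,
                     maxSeparation = 200000, outPrefix = NULL,
                     dialect = blastDialect()) {
    if (!file.exists(hitsFile))
        stop("hits file not found: ", hitsFile, call. = FALSE)
    registry <- if (is(pairing, "PairRegistry")) pairing
                else readPairingFile(pairing)
    hits <- readBlastHits(hitsFile, dialect)
    sweep <- sweepCutoffs(hits, registry, cutoffs, maxSeparation)
    if (!is.null(outPrefix)) {
        writeSweep(sweep, paste0(outPrefix, "_sweep.tsv"))
        return(invisible(sweep))
    }
    sweep
}

.openDevice <- function(file, width, height) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
        png = grDevices::png(file, width = width, height = height,
                             units = "in", res = 150),
        svg = grDevices::svg(file, width = width, height = height),
        pdf = grDevices::pdf(file, width = width, height = height),
        stop("unsupported image format: .", ext, call. = FALSE))
}

#' Plot result sets against the theoretical maximum curve
#'
#' Sensitivity-specificity trade-off plot: each labelled point is one
#' (aligner, parameter set, cutoff) evaluation at
#' (percent of reads positioned, percent of reads in tail-to-tail
#' clones); the curve `y = x^2/100` is the theoretical maximum under
#' independent, always-correct positioning. Points above the curve
#' (possible when the two ends' positioning is correlated) are flagged
#' in the legend. The plotted numbers are always written to a same-stem
#' `.tsv` beside the image, so figures are testable by data.
#'
#' @param points data.frame with columns `pctPositioned`,
#'   `pctTailToTail`, `label`; may be empty (curve-only plot).
#' @param file image path (`.png`, `.svg` or `.pdf`), or `NULL` to
#'   return the ggplot object without writing.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
plotTradeoff <- function(points = NULL, file = NULL,
                         width = 6, height = 5) {
    if (is.null(points))
        points <- data.frame(pctPositioned = numeric(),
                             pctTailToTail = numeric(),
                             label = character())
    need <- c("pctPositioned", "pctTailToTail", "label")
    if (!all(need %in% colnames(points)))
        stop("points needs columns ", paste(need, collapse = ", "),
             call. = FALSE)
    bad <- points$pctPositioned < 0 | points$pctPositioned > 100 |
        points$pctTailToTail < 0 | points$pctTailToTail > 100
    if (any(bad))
        stop("percentages must lie in [0, 100]; offending label: ",
             points$label[bad][1L], call. = FALSE)
    curve <- data.frame(x = seq(0, 100, by = 0.5))
    curve$y <- curve$x^2 / 100
    points$label <- ifelse(
        points$pctTailToTail > points$pctPositioned^2 / 100 + 1e-9,
        paste0(points$label, " (exceeds theoretical maximum)"),
        as.character(points$label))
    p <- ggplot2::ggplot() +
        ggplot2::geom_line(data = curve,
            ggplot2::aes(x = .data$x, y = .data$y),
            linetype = "dashed", colour = "grey40") +
        ggplot2::labs(
            x = "Reads positioned (% of total)",
            y = "Reads in tail-to-tail pairs (% of total)",
            colour = NULL) +
        ggplot2::theme_bw()
    if (nrow(points))
        p <- p + ggplot2::geom_point(data = points,
            ggplot2::aes(x = .data$pctPositioned,
                         y = .data$pctTailToTail,
                         colour = .data$label), size = 2.5)
    if (is.null(file)) return(p)
    utils::write.table(points, paste0(.stem(file), ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .openDevice(file, width, height)
    on.exit(grDevices::dev.off())
    print(p)
    invisible(p)
}

#' Histogram of per-read top-hit scores
#'
#' Frequency distribution of each read's best alignment score, the
#' diagnostic used to locate the inflection between the spurious-hit and
#' correct-hit score modes when choosing a cutoff. Several result sets
#' can be overlaid by passing a named list. Plotted numbers go to a
#' same-stem `.tsv` beside the image.
#'
#' @param scores a numeric vector of top-hit scores, a placements
#'   `GRanges` (one score per read is extracted), or a named list of
#'   either for overlays.
#' @param binwidth histogram bin width on the score axis.
#' @param file image path, or `NULL` to return the ggplot object.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
plotScoreHistogram <- function(scores, binwidth = 5, file = NULL,
                               width = 6, height = 4) {
    asScores <- function(x) {
        if (is(x, "GRanges")) {
            mc <- S4Vectors::mcols(x)
            unname(vapply(split(mc$score, mc$readId), max, 0))
        } else as.numeric(x)
    }
    sets <- if (is.list(scores) && !is.data.frame(scores))
        lapply(scores, asScores) else list(scores = asScores(scores))
    if (is.null(names(sets)) || any(names(sets) == ""))
        names(sets) <- paste0("set", seq_along(sets))
    df <- data.frame(
        score = unlist(sets, use.names = FALSE),
        set = rep(names(sets), lengths(sets)))
    if (!nrow(df)) stop("no scores to plot", call. = FALSE)
    p <- ggplot2::ggplot(df,
            ggplot2::aes(x = .data$score, fill = .data$set)) +
        ggplot2::geom_histogram(binwidth = binwidth,
            position = "identity", alpha = 0.6, boundary = 0) +
        ggplot2::labs(x = "Top-hit alignment score",
                      y = "Reads", fill = NULL) +
        ggplot2::theme_bw()
    if (is.null(file)) return(p)
    utils::write.table(df, paste0(.stem(file), ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .openDevice(file, width, height)
    on.exit(grDevices::dev.off())
    print(p)
    invisible(p)
}

.stem <- function(file) tools::file_path_sans_ext(file)

#' Published example tables
#'
#' Two small published reference tables ship with the package as
#' plain-text data: `exampleSweepTable()` returns a score-cutoff sweep
#' (cutoffs 8-100) of ovine BAC-end sequences aligned to the equine
#' genome assembly with contiguous MegaBLAST (word size 8) — columns
#' `cutoff`, `X` (reads with positions), `o` (reads in tail-to-tail
#' clones), `e` (reads predicted in tail-to-tail clones), and the
#' printed `fp_rate`/`fn_rate`; `exampleScoringTable()` returns the
#' effect of MegaBLAST match/mismatch scoring on the same data set —
#' percentages of reads positioned, in tail-to-tail clones, and of
#' positioned reads in tail-to-tail clones. They are used in examples
#' and as fixed inputs for validating the rate formulas.
#'
#' @return a data.frame.
#' @examples
#' tab <- exampleSweepTable()
#' falsePositiveRate(tab$o, tab$e)
#' @export
exampleSweepTable <- function() {
    utils::read.delim(system.file("extdata",
        "mbc8_equine_sweep.tsv", package = "pairTune",
        mustWork = TRUE), comment.char = "#")
}

#' @rdname exampleSweepTable
#' @export
exampleScoringTable <- function() {
    utils::read.delim(system.file("extdata",
        "megablast_scoring_schemes.tsv", package = "pairTune",
        mustWork = TRUE), comment.char = "#")
}
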