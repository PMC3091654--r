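#' Configure the paired-end placement simulator
#'
#' Defaults describe a BAC-end-like experiment: 20000 clones with
#' truncated-normal inserts (mean 160 kb, sd 20 kb, truncated to
#' [10, 200] kb so the standard 200 kb separation cap rarely rejects a
#' true pair) on a 10 x 50 Mb genome; each 600-base end read is
#' positioned with probability 0.8 and, when positioned, placed at its
#' true location with probability 0.9; correct and spurious best hits
#' draw integral scores from two-sided geometric distributions with
#' modes 70 and 45, so a cutoff sweep across 40-100 is informative.
#'
#' @param nChromosomes,chromosomeLength synthetic genome geometry.
#' @param nClones number of clones (two end reads each).
#' @param insertSizeMean,insertSizeSd,insertSizeMin,insertSizeMax
#'   truncated-normal insert-size model, bases.
#' @param readLength end-read length, bases.
#' @param pPosition probability a read receives any placement.
#' @param pCorrect probability a positioned read is placed correctly.
#' @param scoreTrueLocation,scoreFalseLocation,scoreScale score model.
#' @param nDecoyHits mean extra lower-scoring hits per positioned read.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nChromosomes = 10, chromosomeLength = 5e7,
                      nClones = 20000,
                      insertSizeMean = 160000, insertSizeSd = 20000,
                      insertSizeMin = 10000, insertSizeMax = 200000,
                      readLength = 600,
                      pPosition = 0.8, pCorrect = 0.9,
                      scoreTrueLocation = 70, scoreFalseLocation = 45,
                      scoreScale = 10, nDecoyHits = 1, seed = 1) {
    new("SimConfig",
        nChromosomes = as.integer(nChromosomes),
        chromosomeLength = as.numeric(chromosomeLength),
        nClones = as.integer(nClones),
        insertSizeMean = insertSizeMean, insertSizeSd = insertSizeSd,
        insertSizeMin = insertSizeMin, insertSizeMax = insertSizeMax,
        readLength = as.integer(readLength),
        pPosition = pPosition, pCorrect = pCorrect,
        scoreTrueLocation = scoreTrueLocation,
        scoreFalseLocation = scoreFalseLocation,
        scoreScale = scoreScale, nDecoyHits = nDecoyHits,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d clones on %d x %s b, pPosition=%g, pCorrect=%g, seed=%d\n",
        object@nClones, object@nChromosomes,
        format(object@chromosomeLength, big.mark = ","),
        object@pPosition, object@pCorrect, object@seed))
})

.rTruncNorm <- function(n, mean, sd, lo, hi) {
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out < lo | out > hi)
    while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] < lo | out[bad] > hi]
    }
    round(out)
}

# two-sided geometric around an integral mode; floor at 2 so decoy
# scores clamped one below a primary stay positive
.rScore <- function(n, location, scale) {
    p <- 1 / (1 + scale)
    pmax(2, location + stats::rgeom(n, p) - stats::rgeom(n, p))
}

#' Simulate a paired-end data set with known ground truth
#'
#' Generates clones placed uniformly on the synthetic genome with
#' truncated-normal insert sizes; the two end reads of a clone face
#' inward from the insert boundaries, so every clone is tail-to-tail by
#' construction in the truth. Each read is then independently given a
#' best hit with probability `pPosition`; a positioned read is placed at
#' its true location with probability `pCorrect` (score drawn from the
#' true-hit distribution) and otherwise at a uniform random location and
#' strand (score from the spurious-hit distribution). Poisson-many decoy
#' hits, each strictly below the read's best score, are appended so that
#' best-hit selection has something to discard. The same config (and
#' seed) always yields identical output.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements `registry` ([PairRegistry-class]),
#'   `hits` (`GRanges` with `readId`, `score`), and `truth` (data.frame
#'   with one row per read: true location, strand, whether the read was
#'   positioned and whether its best hit is correct).
#' @examples
#' sim <- simulateDataset(simConfig(nClones = 50, seed = 7))
#' sim$registry
#' @export
simulateDataset <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    withr::with_seed(config@seed, .simulate(config))
}

.simulate <- function(cfg) {
    n <- cfg@nClones
    chroms <- paste0("chr", seq_len(cfg@nChromosomes))
    cloneId <- sprintf("BAC%06d", seq_len(n))
    chrom <- sample(chroms, n, replace = TRUE)
    insert <- .rTruncNorm(n, cfg@insertSizeMean, cfg@insertSizeSd,
                          cfg@insertSizeMin, cfg@insertSizeMax)
    cloneStart <- floor(stats::runif(n, 1,
        cfg@chromosomeLength - insert + 1))
    rl <- cfg@readLength
    truth <- data.frame(
        readId = c(paste0(cloneId, ".F"), paste0(cloneId, ".R")),
        cloneId = rep(cloneId, 2L),
        role = rep(c("forward_end", "reverse_end"), each = n),
        trueTarget = rep(chrom, 2L),
        trueStart = c(cloneStart, cloneStart + insert - rl),
        trueEnd = c(cloneStart + rl - 1, cloneStart + insert - 1),
        trueStrand = rep(c("+", "-"), each = n),
        stringsAsFactors = FALSE)
    m <- nrow(truth)
    truth$positioned <- stats::runif(m) < cfg@pPosition
    truth$correct <- truth$positioned &
        stats::runif(m) < cfg@pCorrect
    pos <- which(truth$positioned)
    wrong <- which(truth$positioned & !truth$correct)
    hitTarget <- truth$trueTarget[pos]
    hitStart <- truth$trueStart[pos]
    hitStrand <- truth$trueStrand[pos]
    score <- .rScore(length(pos), cfg@scoreTrueLocation, cfg@scoreScale)
    if (length(wrong)) {
        w <- match(wrong, pos)
        hitTarget[w] <- sample(chroms, length(wrong), replace = TRUE)
        hitStart[w] <- floor(stats::runif(length(wrong), 1,
            cfg@chromosomeLength - rl + 1))
        hitStrand[w] <- sample(c("+", "-"), length(wrong),
                               replace = TRUE)
        score[w] <- .rScore(length(wrong), cfg@scoreFalseLocation,
                            cfg@scoreScale)
    }
    truth$topScore <- NA_real_
    truth$topScore[pos] <- score
    hits <- data.frame(
        readId = truth$readId[pos], target = hitTarget,
        start = hitStart, strand = hitStrand, score = score)
    nDecoy <- stats::rpois(length(pos), cfg@nDecoyHits)
    if (sum(nDecoy)) {
        k <- sum(nDecoy)
        ri <- rep(seq_along(pos), nDecoy)
        decoy <- data.frame(
            readId = truth$readId[pos][ri],
            target = sample(chroms, k, replace = TRUE),
            start = floor(stats::runif(k, 1,
                cfg@chromosomeLength - rl + 1)),
            strand = sample(c("+", "-"), k, replace = TRUE),
            score = pmin(.rScore(k, cfg@scoreFalseLocation,
                                 cfg@scoreScale), score[ri] - 1))
        hits <- rbind(hits, decoy)
    }
    gr <- GenomicRanges::GRanges(
        seqnames = hits$target,
        ranges = IRanges::IRanges(start = hits$start,
                                  width = rl),
        strand = hits$strand,
        readId = hits$readId, score = hits$score)
    registry <- registryFromTable(data.frame(
        read_id = truth$readId, clone_id = truth$cloneId,
        end = truth$role))
    list(registry = registry, hits = gr, truth = truth)
}

#' Closed-form expected rates for a simulator configuration
#'
#' Under the simulator's independence assumptions, and with a genome
#' large enough that mispositioned reads essentially never pair by
#' chance, the expected false-negative rate is `1 - pPosition` (a read
#' is missed exactly when it receives no placement) and the expected
#' false-positive rate is `1 - pCorrect^2`: observed pairs require both
#' ends correct (`o ~ t p^2 c^2`) while the theoretical curve predicts
#' `e = X^2/t ~ t p^2`.
#'
#' @param config a [SimConfig-class].
#' @return named numeric vector `c(fpRate = , fnRate = )`.
#' @examples
#' expectedRates(simConfig(pPosition = 0.8, pCorrect = 0.9))
#' @export
expectedRates <- function(config) {
    stopifnot(is(config, "SimConfig"))
    c(fpRate = 1 - config@pCorrect^2,
      fnRate = 1 - config@pPosition)
}

#' Write a simulation truth table as TSV
#'
#' @param truth the `truth` element of [simulateDataset()]'s result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Emit a placeholder FASTA for the synthetic framework genome
#'
#' Writes uniform-random chromosome sequences matching the configured
#' geometry, for integration tests that want to run a real aligner
#' against the simulated genome. Sequence content is placeholder only
#' (no repeat or divergence model); coordinates, not bases, carry the
#' simulation's information.
#'
#' @param config a [SimConfig-class]; keep `chromosomeLength` small.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
simulateGenomeFasta <- function(config, path) {
    stopifnot(is(config, "SimConfig"))
    if (!requireNamespace("Biostrings", quietly = TRUE))
        stop("Biostrings is required for FASTA output", call. = FALSE)
    seqs <- withr::with_seed(config@seed, {
        vapply(seq_len(config@nChromosomes), function(i)
            paste(sample(c("A", "C", "G", "T"),
                         config@chromosomeLength, replace = TRUE),
                  collapse = ""), "")
    })
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- paste0("chr", seq_len(config@nChromosomes))
    Biostrings::writeXStringSet(dss, path)
    invisible(path)
}
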