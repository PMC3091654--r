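library(GenomicRanges)

# build a hits GRanges from compact per-hit vectors (recycled)
makeHits <- function(readId, target, start, end, strand, score) {
    n <- max(lengths(list(readId, target, start, end, strand, score)))
    GRanges(seqnames = rep_len(target, n),
            ranges = IRanges::IRanges(start = rep_len(start, n),
                                      end = rep_len(end, n)),
            strand = rep_len(strand, n),
            readId = rep_len(readId, n),
            score = rep_len(score, n))
}

# one 12-column BLAST tabular line; minus strand encoded by sstart > send
blastLine <- function(qseqid, sseqid, sstart, send, bitscore,
                      pident = 95, len = 100, mism = 2, gapo = 0,
                      qstart = 1, qend = 100, evalue = 1e-10) {
    paste(qseqid, sseqid, pident, len, mism, gapo, qstart, qend,
          sstart, send, evalue, bitscore, sep = "\t")
}

# registry of n complete clones named C1..Cn with reads Ck.F / Ck.R
makeRegistry <- function(n) {
    registryFromNames(as.vector(rbind(paste0("C", seq_len(n), ".F"),
                                      paste0("C", seq_len(n), ".R"))))
}

# independent brute-force pair-classification oracle: plain arithmetic
# on data.frames, no package geometry code. posA/posB: data.frames with
# columns target, start, end, strand (1-based closed coordinates).
oracleClassify <- function(posA, posB, maxSep) {
    best <- NULL
    for (i in seq_len(nrow(posA))) for (j in seq_len(nrow(posB))) {
        a <- posA[i, ]; b <- posB[j, ]
        if (a$target != b$target) next
        if (a$strand == b$strand) next
        plus <- if (a$strand == "+") a else b
        minus <- if (a$strand == "-") a else b
        if (!(plus$start < minus$start)) next
        span <- max(a$end, b$end) - min(a$start, b$start) + 1
        if (span > maxSep) next
        if (is.null(best) || span < best) best <- span
    }
    if (is.null(best)) list(category = "positioned_not_paired",
                            separation = NA)
    else list(category = "tail_to_tail", separation = best)
}

# random position set on a small genome for property tests
randomPositions <- function(k, chromLen = 1e6, nChrom = 2,
                            width = 500) {
    s <- sample.int(chromLen - width, k, replace = TRUE)
    data.frame(
        target = paste0("chr", sample.int(nChrom, k, replace = TRUE)),
        start = s,
        end = s + width - 1,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
}

posToGRanges <- function(df, nChrom = 2) {
    GRanges(factor(df$target, levels = paste0("chr", seq_len(nChrom))),
            IRanges::IRanges(df$start, df$end), df$strand)
}
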