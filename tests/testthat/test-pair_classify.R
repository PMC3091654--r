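# the single geometry all tests revolve around: a left read on the plus
# strand facing a right read on the minus strand, outer span <= cap
test_that("only the inward-facing strand/order arrangement is tail-to-tail", {
    left <- c(1001, 1600)    # left interval
    right <- c(150001, 150600)
    cases <- expand.grid(aLeft = c(TRUE, FALSE),
                         strandA = c("+", "-"), strandB = c("+", "-"),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cases))) {
        cs <- cases[i, ]
        a <- if (cs$aLeft) left else right
        b <- if (cs$aLeft) right else left
        grA <- GRanges("chr1", IRanges::IRanges(a[1], a[2]), cs$strandA)
        grB <- GRanges("chr1", IRanges::IRanges(b[1], b[2]), cs$strandB)
        # expected by hand: strands must differ and the plus-strand read
        # must be the left one, i.e. exactly 2 of the 8 arrangements
        plusIsLeft <- (cs$aLeft && cs$strandA == "+" && cs$strandB == "-") ||
            (!cs$aLeft && cs$strandA == "-" && cs$strandB == "+")
        expect_identical(isTailToTail(grA, grB, 200000), plusIsLeft,
            info = paste(cs$aLeft, cs$strandA, cs$strandB))
    }
})

test_that("the outer-span cap and same-target requirement are enforced", {
    a <- GRanges("chr1:1001-1600:+")
    expect_true(isTailToTail(a, GRanges("chr1:150001-150600:-")))
    # span 299,600 > 200,000
    expect_false(isTailToTail(a, GRanges("chr1:300001-300600:-")))
    # exactly at the cap is allowed (inclusive)
    expect_true(isTailToTail(a, GRanges("chr1:200000-200600:-"),
                             maxSeparation = 200600 - 1001 + 1))
    expect_false(isTailToTail(a, GRanges("chr2:150001-150600:-")))
    # coincident starts are conservatively rejected
    expect_false(isTailToTail(GRanges("chr1:1001-1600:+"),
                              GRanges("chr1:1001-1600:-")))
})

test_that("clone classification handles ties, rescue and incompleteness", {
    reg <- makeRegistry(3)
    # C1: plain tail-to-tail; C2: forward end tied at two places, only
    # the second rescues the pair; C3: ends on different chromosomes
    pl <- makeHits(
        readId = c("C1.F", "C1.R",
                   "C2.F", "C2.F", "C2.R",
                   "C3.F", "C3.R"),
        target = c("chr1", "chr1",
                   "chr2", "chr1", "chr1",
                   "chr1", "chr2"),
        start = c(1000, 150000,
                  5000, 1000, 150000,
                  1000, 1000),
        end = c(1599, 150599,
                5599, 1599, 150599,
                1599, 1599),
        strand = c("+", "-", "+", "+", "-", "+", "-"),
        score = 60)
    v <- classifyClones(pl, reg)
    expect_equal(as.character(v$category[match(c("C1", "C2", "C3"),
                                               v$cloneId)]),
                 c("tail_to_tail", "tail_to_tail",
                   "positioned_not_paired"))
    expect_equal(v$separation[v$cloneId == "C1"], 150599 - 1000 + 1)

    # an unpositioned end makes the clone incomplete
    v2 <- classifyClones(pl[mcols(pl)$readId != "C1.R"], reg)
    expect_equal(as.character(v2$category[v2$cloneId == "C1"]),
                 "incomplete")
    # every registry clone gets exactly one verdict
    expect_setequal(v$cloneId, cloneIds(reg))
})

test_that("classification is symmetric in the two ends", {
    set.seed(21)
    for (rep in 1:20) {
        pa <- randomPositions(sample.int(3, 1), chromLen = 4e5)
        pb <- randomPositions(sample.int(3, 1), chromLen = 4e5)
        reg <- registryFromNames(c("C1.F", "C1.R"))
        plAB <- c(posToGRanges(pa), posToGRanges(pb))
        mcols(plAB)$readId <- rep(c("C1.F", "C1.R"),
                                  c(nrow(pa), nrow(pb)))
        mcols(plAB)$score <- 60
        plBA <- c(posToGRanges(pb), posToGRanges(pa))
        mcols(plBA)$readId <- rep(c("C1.R", "C1.F"),
                                  c(nrow(pb), nrow(pa)))
        mcols(plBA)$score <- 60
        vAB <- classifyClones(plAB, reg, 200000)
        vBA <- classifyClones(plBA, reg, 200000)
        expect_identical(vAB$category, vBA$category)
        expect_identical(vAB$separation, vBA$separation)
    }
})

test_that("reverse-complementing the framework preserves every verdict", {
    chromLen <- 4e5
    mirror <- function(df) {
        data.frame(target = df$target,
                   start = chromLen - df$end + 1,
                   end = chromLen - df$start + 1,
                   strand = ifelse(df$strand == "+", "-", "+"))
    }
    set.seed(31)
    for (rep in 1:20) {
        pa <- randomPositions(sample.int(3, 1), chromLen = chromLen)
        pb <- randomPositions(sample.int(3, 1), chromLen = chromLen)
        direct <- oracleClassify(pa, pb, 200000)
        grA <- posToGRanges(pa); grB <- posToGRanges(pb)
        grAm <- posToGRanges(mirror(pa)); grBm <- posToGRanges(mirror(pb))
        anyDirect <- any(isTailToTail(
            rep(grA, each = length(grB)),
            rep(grB, length(grA)), 200000))
        anyMirror <- any(isTailToTail(
            rep(grAm, each = length(grBm)),
            rep(grBm, length(grAm)), 200000))
        expect_identical(anyMirror, anyDirect)
        expect_identical(anyDirect,
                         direct$category == "tail_to_tail")
    }
})

test_that("classification agrees with the brute-force oracle", {
    set.seed(41)
    reg <- registryFromNames(c("C1.F", "C1.R"))
    for (rep in 1:50) {
        pa <- randomPositions(sample.int(5, 1), chromLen = 5e5)
        pb <- randomPositions(sample.int(5, 1), chromLen = 5e5)
        maxSep <- sample(c(5e4, 2e5, 5e5), 1)
        pl <- c(posToGRanges(pa), posToGRanges(pb))
        mcols(pl)$readId <- rep(c("C1.F", "C1.R"),
                                c(nrow(pa), nrow(pb)))
        mcols(pl)$score <- 60
        got <- classifyClones(pl, reg, maxSep)
        want <- oracleClassify(pa, pb, maxSep)
        expect_identical(as.character(got$category), want$category)
        if (want$category == "tail_to_tail")
            expect_equal(got$separation, want$separation)
    }
})

test_that("enlarging the cap never demotes a tail-to-tail verdict", {
    set.seed(51)
    reg <- registryFromNames(c("C1.F", "C1.R"))
    caps <- c(1e4, 5e4, 1e5, 2e5, 1e6)
    for (rep in 1:20) {
        pa <- randomPositions(sample.int(3, 1), chromLen = 5e5)
        pb <- randomPositions(sample.int(3, 1), chromLen = 5e5)
        pl <- c(posToGRanges(pa), posToGRanges(pb))
        mcols(pl)$readId <- rep(c("C1.F", "C1.R"),
                                c(nrow(pa), nrow(pb)))
        mcols(pl)$score <- 60
        t2t <- vapply(caps, function(cap)
            classifyClones(pl, reg, cap)$category == "tail_to_tail",
            TRUE)
        expect_true(all(diff(t2t) >= 0))
    }
})

test_that("a placed read missing from the registry is an error", {
    pl <- makeHits("stray.F", "chr1", 100, 159, "+", 60)
    expect_error(classifyClones(pl, makeRegistry(1)), "stray.F")
})
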