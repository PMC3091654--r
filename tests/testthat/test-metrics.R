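test_that("the theoretical curve has its boundary and scaling behaviour", {
    expect_equal(theoreticalPairs(0, 1000), 0)
    expect_equal(theoreticalPairs(1000, 1000), 1000)
    # percent coordinates: y% = (x%)^2 / 100
    expect_equal(100 * theoreticalPairs(50, 100) / 100, 25)
    expect_error(theoreticalPairs(5, 0), "positive")
    expect_error(theoreticalPairs(20, 10), "X <= t")
    # strictly increasing in X, bounded by t
    X <- 0:500; e <- theoreticalPairs(X, 500)
    expect_true(all(diff(e) > 0))
    expect_true(all(e <= 500))
})

test_that("rate formulas reproduce the published sweep rows", {
    tab <- exampleSweepTable()
    fp <- falsePositiveRate(tab$o, tab$e)
    expect_equal(roundHalfAway(fp, 2), tab$fp_rate)
    # fn with the per-row implied total t = X^2/e
    impliedT <- tab$X^2 / tab$e
    fn <- falseNegativeRate(tab$X, impliedT)
    consistent <- !tab$cutoff %in% c(45, 65)
    expect_equal(roundHalfAway(fn[consistent], 2),
                 tab$fn_rate[consistent])
})

test_that("rate edge cases: zero, one, and negative fp with warning", {
    expect_equal(falsePositiveRate(100, 100), 0)
    expect_warning(r <- falsePositiveRate(110, 100), "exceed")
    expect_equal(r, -0.1)
    expect_error(falsePositiveRate(0, 0), "positive")
    expect_equal(falseNegativeRate(500, 500), 0)
    expect_equal(falseNegativeRate(0, 500), 1)
    expect_error(falseNegativeRate(0, 0), "positive")
})

test_that("summaries count reads, pairs and percentages correctly", {
    reg <- makeRegistry(2)
    pl <- makeHits(c("C1.F", "C1.R", "C2.F", "C2.R"),
                   "chr1", c(1000, 150000, 300000, 600000),
                   c(1599, 150599, 300599, 600599),
                   c("+", "-", "+", "+"), 60)
    v <- classifyClones(pl, reg)
    s <- summarizeVerdicts(v, pl, reg)
    expect_equal(pctPositioned(s), 100)
    expect_equal(pctTailToTailOfTotal(s), 50)
    expect_equal(pctTailToTailOfPositioned(s), 50)
    expect_equal(pctClonesTailToTail(s), 50)

    empty <- selectPlacements(pl, scoreCutoff = 100)
    s0 <- summarizeVerdicts(classifyClones(empty, reg), empty, reg)
    expect_equal(pctPositioned(s0), 0)
    expect_equal(pctTailToTailOfPositioned(s0), 0)

    expect_error(summarizeVerdicts(
        data.frame(cloneId = "ghost", category = "incomplete"),
        pl, reg), "ghost")
})

test_that("published scoring-scheme ratios follow from the two percentages", {
    tab <- exampleScoringTable()
    ratio <- 100 * tab$pct_tail_to_tail_of_total / tab$pct_positioned
    expect_equal(roundHalfAway(ratio, 2),
                 tab$pct_tail_to_tail_of_positioned)
})

test_that("every read lands in exactly one of the three categories", {
    set.seed(61)
    sim <- simulateDataset(simConfig(nClones = 400, pPosition = 0.7,
                                     pCorrect = 0.8, seed = 61))
    pl <- selectPlacements(sim$hits)
    v <- classifyClones(pl, sim$registry)
    s <- summarizeVerdicts(v, pl, sim$registry)
    t <- totalReads(sim$registry)
    X <- length(positionedReads(pl))
    o <- 2 * sum(v$category == "tail_to_tail")
    expect_equal(o + (X - o) + (t - X), t)
    expect_true(o <= X && X <= t)
    expect_equal(o %% 2, 0)
    # reads of tail-to-tail clones are all positioned
    t2tReads <- readIds(sim$registry)[
        as.data.frame(sim$registry)$cloneId %in%
            v$cloneId[v$category == "tail_to_tail"]]
    expect_true(all(t2tReads %in% positionedReads(pl)))
})

test_that("a cutoff sweep matches hand-enumerated survivors", {
    reg <- makeRegistry(3)
    # 8 hits over 6 reads; survivors per cutoff enumerated by hand:
    # cutoff 0: all reads placed, C1 and C2 pair, C3 ends on chr1/chr2
    # cutoff 55: C1.R best hit (50) drops -> C1 incomplete, C1.F still
    #            placed; C2 still pairs (60/70); C3.F (80) stays,
    #            C3.R (40) drops -> X = 4, o = 2
    # cutoff 75: only C3.F (80) survives
    hits <- makeHits(
        readId = c("C1.F", "C1.R", "C2.F", "C2.F", "C2.R",
                   "C3.F", "C3.R", "C3.R"),
        target = c("chr1", "chr1", "chr1", "chr1", "chr1",
                   "chr1", "chr2", "chr2"),
        start = c(1000, 120000, 200000, 1000, 320000,
                  500000, 1000, 5000),
        end = c(1599, 120599, 200599, 1599, 320599,
                500599, 1599, 5599),
        strand = c("+", "-", "+", "+", "-", "+", "-", "-"),
        score = c(60, 50, 60, 30, 70, 80, 40, 40))
    sw <- sweepCutoffs(hits, reg, c(0, 55, 75))
    expect_equal(sw$cutoff, c(0, 55, 75))
    expect_equal(sw$X, c(6L, 4L, 1L))
    expect_equal(sw$o, c(4L, 2L, 0L))
    expect_equal(sw$e, sw$X^2 / 6)
    expect_equal(sw$fnRate, (6 - sw$X) / 6)
    expect_equal(sw$fpRate, (sw$e - sw$o) / sw$e)
})

test_that("sweep columns are monotone in the cutoff", {
    set.seed(71)
    sim <- simulateDataset(simConfig(nClones = 300, seed = 71))
    sw <- sweepCutoffs(sim$hits, sim$registry,
                       c(0, seq(40, 100, by = 10)))
    expect_true(all(diff(sw$X) <= 0))
    expect_true(all(diff(sw$o) <= 0))
    expect_true(all(diff(sw$fnRate) >= 0))
    expect_error(sweepCutoffs(sim$hits, sim$registry, numeric()),
                 "cutoff")
})

test_that("display rounding goes half away from zero", {
    expect_equal(roundHalfAway(0.425, 2), 0.43)
    expect_equal(roundHalfAway(-0.425, 2), -0.43)
    expect_equal(roundHalfAway(0.4249, 2), 0.42)
})
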