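---
title: "Evaluating cross-species read placement with paired-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cross-species read placement with paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairTune)
library(GenomicRanges)
```

## The problem

Low-coverage genome projects routinely position their reads on the
assembled genome of a related species to order and orient contigs. The
choice of alignment program and parameters then controls a trade-off:
permissive settings position more reads (higher sensitivity) but more of
those positions are wrong; stringent settings position fewer reads, more
of them correctly. Match scores and e-values alone cannot quantify this
trade-off, because for a cross-species alignment there is no ground
truth to score against.

Paired-end reads supply that ground truth for free. The two end reads of
a BAC clone (BAC-end sequences, BESs) were sequenced inward from the two
ends of a 100–200 kb insert, so in their source genome they always sit
on opposite strands, facing each other, within the insert length. If an
aligner places both ends of a clone on the framework genome in that same
*tail-to-tail* arrangement within a distance cap, both placements are
very probably correct; everything else is unverified. Counting
tail-to-tail clones per (program, parameter set, score cutoff) turns an
unanswerable accuracy question into simple bookkeeping.

## The quantities

With `t` total reads, `X` positioned reads and `o` reads in
tail-to-tail clones (two per clone):

* **Theoretical maximum curve.** If every positioned read were correct
  and the two ends of a clone were positioned independently, each end is
  positioned with probability `X/t`, a clone pairs with probability
  `(X/t)^2`, and the expected number of reads in pairs is
  `e = X^2 / t` — in percent coordinates, `y = x^2/100`
  (`theoreticalPairs()`). Observed counts may exceed the curve slightly
  when the two ends' positioning is positively correlated, e.g. both
  ends falling in well-conserved sequence.
* **False positive rate** `(e - o)/e` (`falsePositiveRate()`): the
  shortfall of observed pairs relative to the prediction; it estimates
  the fraction of positioned reads whose positions are wrong. It is
  deliberately not clamped at zero — a negative value is a diagnostic of
  correlated positioning and is reported with a warning.
* **False negative rate** `(t - X)/t` (`falseNegativeRate()`): the
  fraction of reads left unpositioned.
* All tail-to-tail percentages are denominated in the *full* data set
  (total reads or total clones), never in the positioned subset; the
  positioned-subset ratio exists as the explicitly named
  `pctTailToTailOfPositioned()`.

## The procedure

1. **Parse hits** (`readBlastHits()`). BLAST-style tabular input; the
   subject coordinate order encodes strand (`sstart > send` is minus)
   and is normalised away at the boundary. The internal container is a
   `GRanges` (1-based, closed, explicit strand) — the field's standard
   interval representation — rather than a bespoke coordinate
   convention; the outer-span arithmetic below is identical under both
   conventions. The score used everywhere downstream is a
   dialect-selected column: `bitscore` for stock 12-column tables, a
   trailing raw `score` column when present (`blastDialect(rawScore =
   TRUE)`), since BLAST-family cutoffs in the 40–100 range are raw-score
   scale. Scores from different aligners are treated as opaque,
   per-result-set numbers and never rescaled across result sets.
2. **Select placements** (`selectPlacements()`). Hits below the cutoff
   are discarded first (the cutoff is inclusive; a hit at exactly the
   cutoff survives — the conventional reading, and the convention is a
   single documented place in the code). Each read then keeps *all*
   positions achieving its maximal remaining score: a tie keeps every
   tied location. Tie comparison is exact numeric equality, which is the
   right notion for the integral raw scores the method filters on.
   Coordinate-identical duplicates (repeated HSP lines) are collapsed so
   they cannot double-count.
3. **Classify clones** (`classifyClones()`). A clone with fewer than two
   positioned ends is `incomplete`. Otherwise every combination of the
   two ends' retained positions is tested with `isTailToTail()`: same
   target sequence, opposite strands, the plus-strand position strictly
   left of the minus-strand position (3' ends pointing inward), and
   outer span — `max(end) - min(start) + 1`, the implied insert size —
   at most `maxSeparation` (default 200 kb, the BAC-insert scale; the
   cap is inclusive). If any combination passes, the clone is
   `tail_to_tail` — so a read with tied positions is rescued when *one*
   of its tied positions forms a pair; if none passes, both reads count
   as `positioned_not_paired`. The witness pair reported per clone is
   the passing combination of smallest separation; witness choice never
   affects counts. Coincident start coordinates are conservatively
   rejected: a degenerate fully-overlapping arrangement is not a
   credible insert, and this affects only pathological inputs.
4. **Summarise and sweep** (`summarizeVerdicts()`, `sweepCutoffs()`).
   The sweep re-runs selection → classification → summary per cutoff and
   attaches `e`, fp and fn. Rates are carried at full precision;
   rounding (half away from zero, `roundHalfAway()`, matching how
   reference tables are printed) is display-only, because 2-decimal
   display rounding is lossy enough to make printed tables internally
   inconsistent. If a cutoff leaves nothing positioned, `e = 0` and that
   row's fp is `NA` rather than an error, so one extreme cutoff cannot
   void a whole sweep.
5. **Plot** (`plotTradeoff()`, `plotScoreHistogram()`). The trade-off
   plot draws result sets against `y = x^2/100` and flags points above
   the curve; the histogram of per-read top scores locates the
   inflection between the spurious-score and correct-score modes, the
   natural place to put a cutoff. Every figure writes a same-stem `.tsv`
   of exactly the plotted numbers, so figures are testable by data, not
   pixels.

## The simulator

`simulateDataset()` exists so every rule above is testable end-to-end
with known truth. It emulates placement *behaviour*, not sequences:
clones are dropped uniformly on a synthetic genome, their two end reads
face inward from the insert boundaries (tail-to-tail by construction),
and each read independently receives a best hit with probability
`pPosition`, correct with probability `pCorrect`, otherwise at a uniform
random location and strand. Correct and spurious hits draw integral
scores from two-sided geometric distributions with different modes, and
Poisson-many decoy hits strictly below each read's best score exercise
the best-hit logic without ever changing a placement.

Defaults, chosen once as a realistic BAC-end experiment: 20,000 clones;
inserts truncated-normal, mean 160 kb, sd 20 kb, truncated to
[10, 200] kb so the default 200 kb cap essentially never rejects a true
pair; genome 10 × 50 Mb, which makes the chance-pairing rate of two
mispositioned reads (≲ 2·cap/genome ≈ 10⁻⁴ per clone) negligible
against the effects being measured; read length 600 b; `pPosition =
0.8`, `pCorrect = 0.9`; score modes 45 (spurious) and 70 (correct) with
geometric scale 10, so a 40–100 cutoff sweep is informative. Under
these assumptions the closed forms in `expectedRates()` hold:
`fn = 1 - pPosition` exactly, and `fp = 1 - pCorrect^2` because
`o ≈ t·p²·c²` while `e = X²/t ≈ t·p²`.

```{r rates}
sim <- simulateDataset(simConfig(nClones = 2000, seed = 42))
pl <- selectPlacements(sim$hits)
v <- classifyClones(pl, sim$registry)
summarizeVerdicts(v, pl, sim$registry)
expectedRates(simConfig())
```

What the simulator does *not* model — and therefore what passing tests
do not show about real data: sequence divergence, repeats and
soft-masking (the dominant driver of spurious hits in practice),
correlated positioning of the two ends, chimeric clones, and
insert-size distributions with heavy tails. The simulator validates the
*bookkeeping*; conclusions about a real aligner still require running
that aligner.

Determinism: the seed lives in the `SimConfig` and the generator runs
under a scoped RNG (`withr::with_seed`), so the same config is
byte-identical regardless of surrounding RNG state.

## Numerical and design choices

* **Tie and cutoff conventions**: exact score equality for ties;
  inclusive cutoff; both are single constants in the code and noted
  above.
* **Facing test at coincident starts** resolves to *not* tail-to-tail
  (conservative; degenerate overlaps only).
* **Single-ended clones** stay in the registry and in `t`: the total
  `t` is a count of reads, not 2 × clones, and those reads can be
  positioned even though they can never pair. Strict name parsing is
  the default; lenient parsing records every skipped read.
* **`e` is carried as a real number**, never rounded to an integer
  before rate computation.
* **Problem sizes in the test suite** are the package's own choice of
  smallest-sufficient: geometric/orientation properties use ≤ 5
  positions per end against a brute-force oracle; stochastic rate
  recovery uses 20,000 clones × 10 seeds, where the binomial standard
  error (~0.002 on fn) is far below the effects asserted.

## Limitations

The method evaluates *relative* performance of programs, parameters and
cutoffs on one data set; absolute fp/fn estimates inherit the
independence assumption and drift when end-positioning is correlated
(observed pairs can then exceed the theoretical curve). Reads shorter
than a few hundred bases, very fragmented framework assemblies (scaffold
N50 below the insert length), and aligners whose scores are not
comparable across hits of one run all weaken the interpretation, though
the bookkeeping still runs.
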