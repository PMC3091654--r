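Package: pairTune
Title: Paired-End Evaluation of Cross-Species Read Placement
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores how well an alignment program and parameter set position
    reads from one genome onto the assembly of a related framework genome,
    using paired-end reads (such as BAC-end sequences) whose two ends have a
    known tail-to-tail relationship in the source genome. Implements
    tie-aware best-hit placement under a score cutoff, tail-to-tail pair
    classification with an insert-size cap, the theoretical maximum curve
    e = X^2/t under independent correct positioning, false-positive and
    false-negative rate estimation, score-cutoff sweeps, trade-off and
    score-distribution plots, and a ground-truth simulator of paired-end
    placement behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    data.table,
    ggplot2,
    rlang,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    Biostrings
biocViews: Alignment, Sequencing, QualityControl, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
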