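Package: zgawindow
Title: Cell-Cycle Windows, Mitotic Transcript Abortion, and Zygotic Genome
    Activation in Early Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for studying how rapid embryonic cell cycles
    limit zygotic genome activation. Implements a closed-form model of the
    transcriptional window (interphase minus a post-mitotic lag), the
    length-dependent eclipse time of a primary transcription unit, and the
    resulting time-averaged expression efficiency per cycle; a stochastic
    simulator of polymerase initiation, elongation, and abortion at mitosis
    whose expectation reproduces the closed form; normalization and
    ordination utilities for single-embryo RNA-seq count matrices
    (log2 CPM+1, per-gene scaling, PCA trajectories, fold-change profiles);
    classification pipelines for zygotic-gene identification, the three-way
    response to cell-cycle arrest, maternal-transcript clearance, and
    nucleo-cytoplasmic-ratio versus time dependence from paired
    diploid/haploid profiles; and a seeded synthetic-data generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
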