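Package: polytran
Title: Polysome-Profiling Differential Translation Analysis with Random
    Variance Moderation
Version: 0.1.0
Authors@R:
    person("Mark", "Delgado", email = "polytran@posteo.net", role = c("aut", "cre"))
Description: Differential translation analysis of paired polysome-associated
    and cytosolic expression profiles by per-gene analysis of partial variance
    (ANCOVA of polysomal on cytosolic log2 expression) with random variance
    model empirical-Bayes moderation, Benjamini-Hochberg false discovery rate
    control, slope-reliability and effect-size filters. Includes
    interferon-stimulated gene (ISG) calling from cytosolic differential
    expression at a linear fold-change threshold, classification of
    transcription start site (TSS)-anchored 5' sequences into TOP, TOP-like
    and non-TOP motif classes, hypergeometric gene-set overlap enrichment,
    polysomal-to-cytoplasmic ratio statistics, and a seeded synthetic-data
    generator that emulates a paired two-fraction microarray design with
    planted gene classes for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
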