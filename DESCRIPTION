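Package: txbench
Title: Benchmarking Toolkit for Long-Read Transcript Detection and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates long-read RNA-seq transcript models and abundance
    estimates against a reference annotation and against ground truth.
    Classifies transcript models into structural categories (full splice
    match, incomplete splice match, novel in catalog, novel not in catalog)
    by comparing intron chains and splice sites to an indexed reference
    catalog, with orthogonal end support from CAGE and 3' end sequencing
    peaks and short-read junction coverage.  Scores detection submissions
    against ground-truth transcript sets (sensitivity, precision, positive
    detection rate, redundancy) and computes cross-submission agreement over
    unique junction chains.  Implements a full suite of quantification
    evaluation statistics with and without ground truth: Spearman
    correlation, median relative difference, normalized root mean square
    error, irreproducibility measure and coefficient-of-variation curves,
    consistency curves, resolution entropy, percentage of expressed
    transcripts, and the exon-isoform matrix condition number, plus a
    two-component cell-mixing evaluation design.  Ships a seeded synthetic
    data generator that emulates every required input so the whole pipeline
    is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
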