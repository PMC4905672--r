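Package: lincseek
Title: Identification, Classification and Stress-Response Profiling of Long
    Noncoding RNAs in Polyploid Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification of long
    noncoding RNAs (lncRNAs) from assembled transcript models: a five-step
    filtration (size, expression, known-isoform overlap, open reading frame,
    coding potential), positional classification into lincRNA / intronic /
    antisense classes with subgenome attribution, FPKM quantification and
    negative-binomial differential expression across a
    control/drought/re-watering design, multi-contrast response-pattern
    categorization, cis (genomic window) and trans (co-expression) target
    prediction, small-RNA precursor and repeat-overlap summaries, and a
    synthetic-data generator that plants ground truth for every stage so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
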