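Package: taclass
Title: Classification of Type II Toxin-Antitoxin Operons from RNA-seq Coverage
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial type II toxin-antitoxin (TA) operons into
    four regulatory classes from operon organization, replicate RNA-seq
    antitoxin-to-toxin coverage ratios, base-resolution coverage changepoints
    (internal promoters and transcript truncation), and a two-of-three
    consensus over translation-initiation-rate predictions. Includes RPKM
    quantification with fractional multi-mapped reads, a two-direction
    (ratio/magnitude) replicate log-error analysis, a surrogate
    Shine-Dalgarno window scorer, a fully labelled synthetic-data generator
    for end-to-end validation, and a curated ten-system Escherichia coli K-12
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
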