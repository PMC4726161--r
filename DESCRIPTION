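Package: mitescan
Title: Genome-Wide Detection of Miniature Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects miniature inverted-repeat transposable elements (MITEs)
    in genome assemblies. Candidate elements carrying a terminal inverted
    repeat (TIR) pair flanked by a target site duplication (TSD) are
    enumerated exhaustively with a complex-number prefix-sum screen,
    false positives are removed with Lempel-Ziv sequence-complexity and
    TIR-composition filters, surviving candidates are clustered into
    families under identity and coverage thresholds, family members are
    validated by divergence of their genomic flanks, and one representative
    copy with exact genome coordinates is selected per family. A synthetic
    genome simulator with a machine-readable truth table supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
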