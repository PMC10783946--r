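Package: fbquant
Title: Feature-Barcode Quantification, Barcode-Design QC and Error Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies feature-barcode sequencing assays (antibody capture,
    sample hashing, CRISPR guide capture) by expanding a barcode whitelist
    into all single-base substitution variants (a mismatch map), scanning
    tag reads at every offset against that map, correcting cell barcodes
    against an on-list, deduplicating UMIs and emitting a sparse cells x
    features count matrix in MatrixMarket format. Also provides a barcode
    design quality-control report (code-diversity bounds, shared
    subsequences, pairwise Hamming distance histograms, homopolymer runs,
    per-position nucleotide content) and a substitution-error simulation
    that reports the fraction of barcode reads lost or misassigned at a
    given per-base error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
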