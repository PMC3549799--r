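Package: cliptar
Title: miRNA Target Site Discovery from CLIP and PAR-CLIP Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A six-stage pipeline that turns raw CLIP or PAR-CLIP sequencing
    reads into ranked miRNA-target interactions on 3'UTR reference sequences:
    3' adapter and quality trimming, duplicate read collapsing, a
    one-cytidine-at-a-time C-to-T reversion strategy that recovers reads
    carrying crosslink-induced T-to-C conversions under a one-mismatch
    alignment budget, exact ungapped k-mer/pigeonhole alignment to 3'UTRs,
    single-linkage read clustering with read-support and conversion-fraction
    filters, canonical seed-match site identification (8mer, 7mer-m8,
    7mer-A1) with evidence-based ranking, and per-position T-to-C conversion
    profiles with a one-tailed regional Student's t test. Includes a
    synthetic PAR-CLIP read generator with a ground-truth table so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
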