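Package: cnmatch
Title: Matching DNA Copy Number Array Features to Expression Array Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the integrative analysis of paired DNA copy number
    (aCGH) and gene or microRNA expression microarray data. Implements six
    procedures for assigning copy number features to expression features
    (label, distance, distanceAny, overlap, overlapAny, overlapPlus),
    weighted and most-aberrant summarization of multi-feature matches with
    breakpoint-aware splitting, a downstream cis-effect stage based on
    Spearman rank correlation with Benjamini-Hochberg correction and
    pairwise procedure comparison, a seeded simulator of paired platforms,
    and TSV/BED readers and writers with a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
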