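Package: kinomescan
Title: Profile-Based Kinome Annotation, Classification and Census
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies protein-kinase-like sequences in predicted proteomes
    using position-specific scoring matrix (PSSM) searches with empirically
    calibrated E-values, separates functional kinases from protein-kinase-like
    non-kinases (PKLNKs) with a motif filter cascade (sequence length,
    glycine-rich loop, catalytic-loop aspartate, RD status), assigns kinases to
    Hanks-Hunter groups and subfamilies by an identity/coverage rule, computes
    kinome census statistics, analyses domain architectures including
    twin-kinase detection and hydropathy-based transmembrane prediction for
    receptor kinases, builds identity-distance clusters and neighbor-joining
    dendrograms, and maps pathway homolog presence (close/remote/absent).
    Ships a synthetic-proteome generator with full ground truth so every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    ape,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
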