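Package: isoresolve
Title: Reconstructing Transcripts of Highly Similar Multigene Families from
    Long-Read Iso-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives exact transcript sequences from full-length PacBio circular
    consensus (CCS) reads of highly similar multigene-family transcripts.
    Implements iterative nearest-neighbor clustering with partial consensus-based
    error correction, a quality-weighted hypothesis test with a Chernoff-type
    tail bound for removing spurious candidate transcripts, grouping of final
    transcripts into putative gene copies via maximal cliques, and a targeted
    CCS read simulator with exact-match recall and precision evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
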