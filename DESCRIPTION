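Package: nanometabar
Title: DNA Metabarcoding of Nanopore Amplicon Reads with Consensus Error
    Correction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying species in mixed-template amplicon
    sequencing runs from long-read nanopore devices. Raw reads are
    quality- and length-filtered, assigned to barcode markers by
    error-tolerant IUPAC-aware primer matching, clustered greedily at a
    fixed identity threshold, error-corrected by majority-rule consensus
    over a center-star multiple sequence alignment, and assigned to
    taxa by local alignment against an annotated reference set with
    identity and coverage thresholds. Marker-level identifications are
    combined into per-taxon final conclusions. A read simulator with a
    tunable substitution/insertion/deletion error model makes every
    stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
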