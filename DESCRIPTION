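Package: mirwound
Title: Small RNA Quantification, miRNA Precursor Discovery, Target
    Prediction and Cleavage-Site Mapping for Plant Wounding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the computational chain used to characterize
    wound-responsive microRNAs in plants from small-RNA sequencing
    libraries and a de novo transcriptome: read collapsing and
    reads-per-million quantification with fold-change classification of
    wound-inducible and wound-repressible miRNAs; identification of
    precursor hairpins in transcriptome contigs by exact mature-sequence
    matching and weighted maximum base-pairing folding with miRNA* strand
    prediction; penalty-score target prediction (1 point per mismatch,
    0.5 per G:U wobble, 2 per gap, candidates at <= 3 points with no
    central-region mismatch); and tallying of RACE-determined cleavage
    sites relative to the miRNA 5' end. A seeded synthetic-data generator
    emulates two-condition read libraries, precursor- and target-bearing
    contigs, and RACE clone sets so that every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
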