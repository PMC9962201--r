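Package: arcp450
Title: Annotation and Comparative Genomics of Archaeal Cytochrome P450s and
    Their Redox Partners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide mining and annotation of
    cytochrome P450 monooxygenases (CYPs) and their redox partners in
    prokaryotic, in particular archaeal, proteomes. Detects P450 candidates by
    the conserved EXXR and CXG signature motifs and filters fragments below a
    length cutoff; assigns CYP family and subfamily labels from pairwise
    global-alignment percent identity using the standard 40%/55% nomenclature
    thresholds; classifies ferredoxins into iron-sulfur cluster types and
    cysteine-spacing subtypes; detects 2-oxoacid:ferredoxin oxidoreductase
    (OFOR) alpha/beta subunit gene pairs; predicts operons from strand and
    intergenic distance; and computes replicon-aware comparative statistics
    (family expansion, family co-presence across species, plasmid versus
    chromosome distributions, family saturation curves) plus a
    neighbor-joining phylogeny from the identity matrix. Includes a
    seed-deterministic synthetic-study generator with full ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
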