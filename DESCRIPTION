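Package: hpotu
Title: Homopolymer-Aware OTU Clustering and Taxonomy for V9 Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for eukaryotic 18S rRNA V9 amplicon
    surveys sequenced on homopolymer-error-prone platforms (454
    pyrosequencing). Reads are retained only when both amplification primers
    match exactly, strictly dereplicated, and clustered into OTUs by an
    abundance-greedy algorithm under a global-alignment distance in which
    differences that only change homopolymer run lengths are not counted.
    OTUs are assigned taxonomy by a rank walk-up consensus over
    similarity-filtered hits, classified as putatively planktonic via
    phototroph taxon lists and environmental-sequence matches, and summarised
    into cross-sample occupancy and region-sharing tables. A synthetic-data
    generator with full ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
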