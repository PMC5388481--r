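Package: barcodeEval
Title: Evaluation of Candidate DNA Barcode Loci for Species Discrimination
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate candidate DNA barcode loci for their power to
    discriminate species, built around per-locus aligned sequence matrices and
    specimen metadata. Computes alignment summary statistics (variable and
    parsimony-informative sites, indel events), pairwise p and Kimura
    2-parameter distances with pairwise or complete deletion, per-species
    barcode-gap summaries (maximum intraspecific distance versus minimum
    nearest-neighbour distance), neighbour-joining trees with nonparametric
    bootstrap support, species monophyly tests, and multilocus concatenation
    analyses over shared specimens. Includes a sequence simulator with known
    truth (species tree, transition/transversion ratio, per-locus amplification
    dropout) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    seqinr,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
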