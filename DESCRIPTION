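Package: palmprintR
Title: Viral RdRP Palmprint Barcode Detection, Extraction and Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects the conserved A, B and C catalytic motifs of viral
    RNA-dependent RNA polymerases (and reverse transcriptases) in amino
    acid or nucleotide sequences using position-specific scoring matrices,
    extracts the motif-delimited "palmprint" barcode segment with a
    heuristic confidence score, clusters palmprints into species-like
    operational taxonomic units by global-alignment identity, tunes the
    species identity threshold against taxonomy labels, and provides a
    validation harness (sensitivity, PPV/FDR, random-sequence decoy
    scans) together with a synthetic-fixture generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, Alignment, Classification, Metagenomics
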