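Package: tadscape
Title: Fragment-Resolution Hi-C Domain Analysis for Compact Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing restriction-fragment-resolution Hi-C contact
    maps of compact genomes such as Drosophila melanogaster. Provides in
    silico genome digestion, sparse contact-matrix containers with iterative
    correction (ICE) balancing, Armatus-style dynamic-programming annotation
    of topologically associating domains (TADs) with a read-desert fallback,
    boundary-centred insulator-protein enrichment statistics with a shuffled
    background, logistic-regression prediction of border fragments,
    k-means chromatin-state typing of domains, distance-normalised
    intra- and inter-TAD contact enrichment metrics, and a seeded synthetic
    Hi-C generator that plants known nested domain structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
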