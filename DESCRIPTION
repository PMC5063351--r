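Package: sinescout
Title: Detection, Annotation and Classification of SINE Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An annotation pipeline for short interspersed nuclear elements
    (SINEs) in fungal genomes. Detects the structural hallmarks of SINE
    insertions (target site duplications, internal RNA polymerase III
    promoter boxes, oligo-T and simple-repeat tails, termination signals),
    classifies candidate elements as tRNA-derived (SINE2) or 5S rRNA-derived
    (SINE3) by head homology to reference gene sets, and maps element copies
    across genome contigs by seed-and-extend local alignment. Ships the
    catalogue of thirteen AfuSINE elements described from the Aspergillus
    fumigatus Af293 genome, and a synthetic-genome simulator that plants
    elements with known ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
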