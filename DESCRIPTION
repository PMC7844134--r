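Package: pgcfinder
Title: Detection and Classification of Photosynthesis Gene Clusters in
    Gemmatimonadetes Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes chlorophototrophic Gemmatimonadetes bacteria (CGB)
    from annotated genomes and metagenome-assembled genomes (MAGs).
    Assigns proteins to photosynthesis-related gene families by local
    alignment with BLAST-like significance and coverage thresholds, chains
    assigned genes into photosynthesis gene cluster (PGC) candidates,
    segments clusters into the canonical sub-cluster architecture and
    tests the Gemmatimonadetes-specific acsF and bchO placement markers,
    applies marker-based CGB membership and oxygen-lifestyle rules and
    identity-threshold taxonomic delimitation, compares PGCs by per-gene
    protein identity and nucleotide synteny blocks, and simulates
    annotated genomes and MAG-like fragment sets with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
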