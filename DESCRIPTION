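Package: pseudoscan
Title: Homology-Based Pseudogene Prediction, Classification and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide prediction of pseudogenes from intergenic DNA.
    Parent proteins are searched against the six translated frames of a
    repeat- and gene-masked genome, local hits are chained into candidate
    loci with a unique parent, each locus is re-aligned to its parent with a
    frameshift-, stop- and intron-aware dynamic program, and validated calls
    are classified as processed, duplicated or fragment using intron loss,
    poly-A tails and target-site duplications, with Nei-Gojobori Ka/Ks
    estimation as a set-level validation channel. Includes an overlap-based
    evaluation protocol against known pseudogene annotations, a multi-tool
    comparison report, and a synthetic-genome simulator that implants
    processed, duplicated, unitary and fragment pseudogenes with a
    machine-readable truth set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
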