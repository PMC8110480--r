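Package: lineagescan
Title: Lineage-Specific Evolutionary Signatures from Comparative Genome Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and validates lineage-specific evolutionary signatures
    in comparative genomic data sets: lineage-specific fixed substitutions
    (LSGs) confirmed by marginal ancestral-state reconstruction via
    Felsenstein pruning, lineage-specific conserved noncoding elements
    (SCNEs) from reference-anchored whole-genome alignment blocks,
    branch-model dN/dS (GY94) estimation with likelihood-ratio
    classification of positively selected and rapidly evolving genes,
    Tajima's relative rate test and a two-cluster rate Z test, and k-mer
    based genome-size estimation. Ships simulators with known ground truth
    for every analysis (codon alignments under branch-specific omega,
    planted lineage-specific substitutions, planted conserved noncoding
    elements, k-mer depth histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    phangorn,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Genetics, Alignment, SequenceMatching
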