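Package: liabscan
Title: Single-Step Genomic Threshold Models and Window-Based Genome
    Scans for Binary Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binary disease or fitness outcomes in
    pedigreed livestock populations as threshold (probit) traits.
    Builds pedigree and genomic relationship matrices and the combined
    single-step (ssGBLUP) inverse, fits a Bayesian liability threshold
    animal model with additive-genetic and service-sire random effects
    by Gibbs sampling with data augmentation, back-solves SNP marker
    effects from genomic breeding values, scans the genome with 2.0 Mb
    SNP windows for the share of additive variance they explain, and
    tests user-supplied gene sets for overrepresentation of genes
    tagged by large SNP effects with the cumulative hypergeometric
    test. Includes a synthetic-data generator (pedigree gene-drop,
    liability phenotypes, toy annotations) so the whole pipeline is
    testable without proprietary herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    fgsea,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
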