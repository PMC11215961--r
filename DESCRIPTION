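Package: sparseqtl
Title: Sparse L0+L1 Penalized Selection of Causal cis-eQTL Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects causal cis-eQTL variants from per-gene SNP dosage
    matrices by minimizing a squared-error loss with combined L0 (best
    subset) and L1 (lasso) penalties, optimized by cyclic coordinate
    descent with local combinatorial swap search over a two-dimensional
    regularization path with cross-validated model selection and an
    optional stability-selection ensemble. Ships a simulation framework
    that generates LD-structured genotype panels and gene expression under
    additive, heterogeneous, recessive and compensatory genetic
    architectures with exact heritability calibration; comparator
    selectors (LASSO, elastic net, thresholded ridge, single-variant
    association with per-gene Bonferroni control); an F1-based benchmark
    harness; pairwise eQTL-set similarity; and per-variant genotype-class
    ANOVA of expression. Reads genotype panels from PLINK bed/bim/fam or
    VCF and expression from TSV or expression-BED tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    glmnet,
    vcfR,
    data.table,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
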