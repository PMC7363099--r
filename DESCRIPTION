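Package: tauGWAS
Title: Encoding-Robust Association Testing for Continuous Phenotypes
    with Kendall's Tau
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association testing of continuous phenotypes that is
    robust to the numeric encoding of bi-allelic genotypes. After PCA-based
    correction for population stratification, ordinally encoded genotypes
    become continuous and the usual Pearson slope test depends on the encoding
    chosen (e.g. {0,1,2} versus {-1,0,1}). tauGWAS implements the PCA residual
    adjustment with its additive-shift remainder, a non-parametric per-SNP
    association test based on Kendall's tau with O(n log n) merge-sort
    concordance counting, Pearson and Spearman comparators, a fully specified
    genotype-phenotype simulator (Hardy-Weinberg draws, variance-partition
    phenotype model, partial shuffling), and robustness/power diagnostics:
    encoding p-value differences with their skewness and kurtosis, sample-pair
    rank-preservation ratios, and analytic power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
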