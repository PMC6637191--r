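Package: snpML
Title: Machine Learning Classification and Locus-Importance Robustness for
    Case-Control Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study polygenic case-control classification from SNP
    genotypes and the stability of the genomic loci the classifiers deem
    important. Provides a synthetic genotype simulator with linkage
    disequilibrium, non-uniform marker density and differential missingness;
    PLINK bed/bim/fam input and output; quality control, Hardy-Weinberg
    based imputation and several genotype codings; single-SNP association
    screening with four chi-squared tests; adapters for penalized logistic
    regression, gradient boosted trees, dense and residual neural networks
    and a random-weight null model; permutation, weight and gain feature
    importance aggregated to fixed 500 kb loci; and robustness and overlap
    statistics for ranked locus lists across data folds and models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SNP, Classification, FeatureExtraction, GenomeWideAssociation
RoxygenNote: 7.3.3
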