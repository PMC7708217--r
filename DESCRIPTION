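Package: methylMRM
Title: DNA Methylation Imputation with Mixtures of Radial Basis Function
    Regressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Imputes DNA methylation levels at unmeasured CpG sites from
    low-coverage bisulfite data (RRBS, sparse WGBS) by modelling regional
    methylation profiles as a finite mixture of radial basis function
    regressions fitted by a penalized EM algorithm. Cluster number is
    selected by the integrated completed likelihood (ICL) and the lasso
    penalty by cross-validation. A regional model (clustering subjects
    within a region) and a subject model (clustering regions within a
    subject) are combined by non-negative stacked regression. Includes a
    model-based simulator with known ground truth, correlation-based
    region definition and filtering, weighted-neighbour and KNN baseline
    imputers, and an evaluation harness (RMSE, correlation, AUC, paired
    t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    pROC,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    withr,
    knitr
Config/testthat/edition: 3
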