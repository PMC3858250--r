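Package: survMRS
Title: Molecular Risk Scores for Survival After Resection of Colorectal
    Liver Metastases
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised principal-component survival modelling for gene
    expression cohorts. Screens genes by univariate Cox (or Fine-Gray
    subdistribution) regression, selects a significance threshold by
    cross-validation, extracts the first principal component of the
    selected genes to form a molecular risk score (MRS), and validates
    the frozen score on held-out samples by Kaplan-Meier estimation,
    log-rank testing, Harrell's concordance index and multivariate Cox
    models alongside the five-factor clinical risk score (CRS) for
    resected colorectal liver metastases. Includes a synthetic-cohort
    generator with known planted prognostic genes, quantile
    normalization with a frozen training reference, and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    SummarizedExperiment,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    rlang
Suggests:
    cmprsk,
    limma,
    optparse,
    testthat (>= 3.0.0)
biocViews: Survival, GeneExpression, Microarray, DimensionReduction,
    Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
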