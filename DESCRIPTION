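Package: gsresp
Title: Genomic Prediction and Selection Response for Multi-Environment
    Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection analysis of diverse crop
    collections evaluated in multi-environment field trials: marker
    quality control and VanRaden genomic relationship matrices, stage-one
    spatial adjustment of plot data with separable AR1xAR1 residuals,
    REML estimation of univariate, multi-trait and genotype-by-environment
    GBLUP models on accession BLUEs, five-fold cross-validated prediction
    accuracy under multi-trait CV1/CV2 scenarios, and comparison of
    phenotypic and genomic selection indices (including Smith-Hazel
    weights) through selection differentials and responses. Includes a
    synthetic-data module that simulates genotypes, additive and
    site-interaction effects, and spatially correlated plot phenotypes
    with known covariance structure so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
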