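Package: menvgp
Title: Multi-Environment Genomic Prediction with Spatial Field-Trial Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of quantitative traits measured in
    multi-environment field trials of inbred lines. Provides P-spline
    (PS-ANOVA) spatial adjustment of row-column trials to obtain genotype
    best linear unbiased estimators (BLUEs), marker quality control and
    VanRaden genomic relationship matrices, environmental-covariate kernels,
    and five Bayesian whole-genome regression models fitted by Gibbs
    sampling: single-environment GBLUP, a genotype-by-covariate reaction-norm
    model, the marker-by-environment interaction model in its GBLUP
    parameterization, and multi-trait models with unstructured
    between-environment genetic covariance (with and without a
    marker-independent genetic component). Includes sparse-testing
    cross-validation designs (single-environment, CV1, CV2), predictive-
    ability summaries, paired one-sided model comparisons, and a synthetic
    data generator with known breeding values for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
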