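Package: neuroage
Title: Sex-Stratified Brain-Age Modelling with Biomarker Validation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating biological brain age from regional
    structural neuroimaging features and validating the resulting
    brain-age delta against biomarkers of Alzheimer's disease and
    neurodegeneration.  Includes a synthetic multi-cohort generator with
    known ground truth, covariate residualization and within-cohort
    standardization, a sex-stratified gradient-boosted tree regressor
    with exact tree-Shapley region attributions and a
    stability/permutation significance procedure, linear age-bias
    correction, amyloid/tau (AT) biomarker staging with published
    cut-offs, and a covariate-adjusted association battery with
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
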