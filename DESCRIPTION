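Package: lipidmr
Title: Mendelian Randomization of Blood Lipid Genotype Risk Scores on Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for Mendelian randomization of blood lipid
    levels on late-onset Alzheimer disease risk using weighted genotype risk
    scores (GRS). Implements weighted full and trait-specific GRS
    construction from dosage data, lipid phenotype preparation (unit
    conversion, covariate residualization, rank-based inverse-normal
    transformation), two-stage instrumental-variable estimation (the
    individual-level ratio estimator with delta-method standard errors and
    the summary-statistics inverse-variance weighted estimator), an
    instrument-strength gate on the first-stage R-squared, fixed- and
    random-effects inverse-variance meta-analysis across cohorts with
    heterogeneity statistics, study-design calculations (expected effect
    size and power), and a multi-cohort case-control simulator with known
    causal truth for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
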