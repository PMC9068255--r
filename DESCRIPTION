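Package: probastmeta
Title: Methodological Quality of Prediction Models and Performance at External Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-epidemiological synthesis relating the methodological
    quality of clinical prediction-model development studies to their
    discriminative performance at external validation. Implements a
    mechanical PROBAST rollup (signaling answers to domain judgments to
    overall risk of bias and applicability, an 8-item short form, and the
    events-per-parameter rule), the paper-style bespoke rubrics
    (relatedness, usability, design similarity), the percent change in
    discrimination (dAUC) statistic with stratified median/IQR summaries,
    a clustered Gaussian generalized estimating equations (GEE)
    meta-regression with robust sandwich variance, and a seeded generator
    of synthetic evidence bases with binormal validation AUCs for
    end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
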