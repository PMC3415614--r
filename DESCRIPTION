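Package: healthexp
Title: Sullivan-Method Health Expectancy for Cancer-Registry Survivor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes abridged period life tables, age-specific prevalence of
    poor self-rated health and walking disability, and Sullivan-method healthy
    and disability-free life expectancy (HLE/DFLE) from person-level
    cancer-registry survival records joined to a cross-sectional quality-of-life
    survey. Includes Lexis-style person-time splitting over an observation
    window, stratified reporting at chosen ages, a multivariate logistic
    determinants analysis with adjusted odds-ratio tables, Kaplan-Meier
    survival summaries by stage, and a synthetic registry/survey generator with
    Gompertz background mortality plus stage-specific excess hazards so every
    stage of the pipeline can be validated against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
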