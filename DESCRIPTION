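Package: oxbal
Title: Oxidative Balance Scores and Survey-Weighted Telomere Length Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction of composite oxidative balance scores (OBS) from
    twenty dietary and lifestyle components with sex-specific tertile point
    assignment, NHANES-style cohort exclusion pipelines with attrition
    logging, qPCR telomere T/S-ratio replicate and run-level quality
    control, and survey-weighted linear regression with Taylor-linearization
    variance estimation for stratified multistage samples.  Provides
    quartile and trend analyses, dietary and lifestyle sub-scores,
    leave-one-component-out sensitivity analysis, report generation, and a
    synthetic survey-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), sandwich, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
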