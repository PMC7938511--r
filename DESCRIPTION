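Package: voe
Title: Vibration of Effects for Model, Sampling and Measurement Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the stability of an exposure-mortality association
    estimated with Cox proportional-hazards regression under three sources of
    analytic uncertainty: the choice of adjustment variables (model vibration),
    subsampling of the cohort (sampling vibration), and simulated measurement
    error or misclassification in the covariates (measurement vibration).
    Results are summarized by relative hazard ratios, relative P-values,
    significance classification and Janus-pattern detection, and displayed as
    volcano plots. Includes a synthetic survival-cohort generator with
    correlated mixed-type covariates for simulation studies across sample
    sizes, and a command-line interface for scripted runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
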