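Package: pocagree
Title: Agreement Statistics for Point-of-Care Analyzer Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Method-comparison statistics for validating point-of-care (POC)
    glucose and beta-hydroxybutyrate meters against reference laboratory
    methods, as applied in elasmobranch clinical pathology. Implements
    replicate precision (CV%), percent bias, Westgard-style observed total
    error, relative-error zoning against FDA glucometer thresholds,
    Bland-Altman limits of agreement with confidence intervals,
    Passing-Bablok rank regression with nonparametric confidence intervals
    and constant/proportional bias flags, and a random-intercept linear
    mixed-model covariate screen for meter-minus-reference differences.
    Includes half-LLOQ imputation for left-censored readings, long-format
    CSV input/output, a synthetic validation-study generator with
    constant-plus-proportional device bias and heteroscedastic noise, and
    report assembly in the field's standard table layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
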