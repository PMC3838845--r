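Package: rocsel
Title: Grouped Variable Selection and Focused Model Selection for ROC Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Variable selection for covariate-specific ROC analysis under the
    induced methodology, where Gaussian linear models are fitted separately to
    diseased and non-diseased test results and the area under the ROC curve
    (AUC) at a covariate profile is derived from them. The two per-group models
    are fused into a single weighted least-squares problem in which each
    covariate contributes a two-coefficient factor, so that a group SCAD
    penalty selects or drops a covariate simultaneously in both groups. Tuning
    parameters can be chosen by 5-fold cross-validation, GCV, AIC, or a BIC
    selector that consistently recovers the narrow model, and a two-stage
    focused information criterion (FIC) procedure targets the precision of the
    estimated AUC at a given profile. Includes a simulation engine for
    local-misspecification study designs, CSV input/output, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
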