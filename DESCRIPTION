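Package: hcysgm
Title: Subcortical Covariance Pattern Analysis and Serial Mediation for
    Vascular Cognitive Aging Studies
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for ROI-based brain morphometry studies of
    vascular risk and cognitive aging.  Implements the Scaled Subprofile
    Model (SSM) variant of principal component analysis to derive a
    biomarker-predicting regional covariance pattern from a subjects-by-
    regions volume matrix, with AIC-based sequential component selection and
    bootstrap reliability estimates of the regional weights; block-wise
    multiple regression of lobar gray matter volumes with standardized
    coefficients and Benjamini-Hochberg false discovery rate correction;
    serial mediation models with one to three ordered mediators, percentile
    bootstrap confidence intervals and completely standardized indirect
    effects; and a synthetic cohort generator that emulates the marginal
    distributions and hypothesized causal chain of a healthy-aging cohort so
    the full pipeline is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
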