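Package: microflight
Title: EEG Microstate Analysis for Longitudinal Training Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for EEG microstate analysis of multi-session training
    cohorts: rule-based preprocessing (FIR band-pass filtering, bad-channel
    detection, FASTER-style epoch statistics, spherical-spline channel
    interpolation, average referencing, resampling), polarity-invariant
    modified k-means clustering of global-field-power peak topographies with
    cross-validation model selection, hierarchical group-level map
    aggregation, template backfitting, extraction of the coverage, duration
    and occurrence temporal parameters, and a statistics layer with
    repeated-measures ANOVA (Greenhouse-Geisser corrected), Bonferroni paired
    t-tests and Spearman brain-behavior correlation. Includes a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
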