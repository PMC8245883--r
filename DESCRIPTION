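Package: telosim
Title: Simulation-Based Assessment of Telomere-Length Assay Precision for
    Longitudinal Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates two-timepoint leukocyte telomere length (LTL) cohorts
    with a gold-standard truth track (Southern-blot-like, kilobases) and an
    error-prone proxy track (qPCR-like, unitless) whose cross-sectional
    validity correlation with truth is configurable. Computes per-cohort
    measurement-error signature statistics (method-agreement correlations for
    baseline, follow-up and change; regression-to-the-mean baseline-change
    correlations; apparent-lengthening fractions) and replicates them over
    many simulated cohorts. Estimates the statistical power of three pre-post
    analysis strategies (cross-section, difference score, ANCOVA) on each
    assay track over a grid of sample sizes. Includes the correlation,
    Fisher-z comparison, one-sample t and one-way intraclass-correlation
    utilities needed for worked examples on published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
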