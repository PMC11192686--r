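Package: itasense
Title: Sensitivity Comparison for Indirect Task Advantages
Version: 0.1.0
Authors@R:
    person("Jonas", "Keller", email = "jonas.keller@posteo.net", role = c("aut", "cre"))
Description: Tools to test whether an indirect, reaction-time based measure of
    recognition carries more signal-detection sensitivity than participants'
    direct (explicit report) measure -- an Indirect Task Advantage (ITA).
    Implements the median-split ideal-observer analysis of trial-level search
    reaction times, an unbiased estimator of indirect sensitivity from
    reported paired t statistics based on noncentral-t moments, estimation of
    the between-subject to trial-level variance ratio, frequentist and
    one-sided default-prior (JZS) Bayesian sensitivity comparisons, bootstrap
    tests of individual-participant sensitivity differences, funnel-plot
    coordinates, and a single-source simulation engine for calibration and
    recovery studies of contextual-cueing style experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
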