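Package: mwlfusion
Title: Multi-Measure Mental Workload Analysis for Multi-UAV Supervision Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating operator mental workload during one-to-many
    unmanned-aircraft supervision sessions from synchronized physiological and
    behavioural data streams. Implements an EEG theta/alpha spectral workload
    index (bandpass filtering, windowed Welch power spectral density, band
    integration, outlier replacement and smoothing), a gaze-transition visual
    entropy measure over screen regions of interest, a pending-secondary-task
    index scored from vehicle flight logs, controller-input counts, weighted
    fusion of the physiological measures, and phase-level one-way ANOVA with
    Tukey HSD plus pairwise Pearson correlation summaries. A deterministic
    synthetic session generator emulates every input stream from a latent
    workload profile, so the full pipeline can be exercised, validated and
    benchmarked without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
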