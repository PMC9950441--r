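Package: confclust
Title: Single-Trial EEG Markers of Confidence and Error Monitoring Under
    Performance Matching
Version: 0.1.0
Authors@R:
    person("Martin", "Delatte", email = "m.delatte@posteo.net",
           role = c("aut", "cre"))
Description: A reusable pipeline for studying electrophysiological markers
    of confidence and error monitoring (error-related negativity and
    related potentials) in performance-matched two-group designs.
    Provides mouse-kinematic trial processing (movement-onset detection,
    change-of-mind flags, exclusion rules), deterministic EEG epoch
    preprocessing (band-pass filtering, common-average reference,
    participant-level baseline correction, amplitude-percentile trimming,
    variance-based participant exclusion), a three-step mass-univariate
    statistical procedure (per-sample per-electrode linear mixed-model
    scans with false-discovery-rate correction, region-of-interest
    cluster regressions with nested random effects and a temporal
    contiguity rule, peak-window effect amplitudes), cluster-level
    Bayesian mixed models with directional evidence ratios and
    Savage-Dickey null-support Bayes factors, behavioural metacognition
    (signal-detection d-prime, maximum-likelihood and hierarchical
    Bayesian meta-d-prime / M-ratio, JZS default Bayes factors), and a
    synthetic-data generator emulating a staircase-matched two-group
    motion-discrimination experiment so that every stage is testable
    without any external recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
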