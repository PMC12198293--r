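Package: betatrack
Title: Word-Onset Tracking in Basal Ganglia Beta-Band Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Temporal response function (TRF) analysis of word-onset
    tracking in the beta-band (12-30 Hz) Hilbert envelope of basal ganglia
    local field potentials recorded during two-speaker speech. Provides a
    synthetic-session generator with known ground-truth kernels, LFP
    preprocessing (bipolar re-referencing, epoching, z-score artifact
    rejection, correct-trial retention), multitaper time-frequency power
    with percent-change baselining, lagged ridge-regression TRF estimation
    with five-fold cross-validated prediction correlation, and
    resampling-based inference: a trial bootstrap of real tracking, an
    interval-preserving onset shuffle null, per-contact empirical p-values,
    and cohort-level contact counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
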