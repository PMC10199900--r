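Package: porecall
Title: Simulation and Analysis of Single-Amino-Acid Nanopore Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying single-amino-acid identification in
    atomically thin solid-state (MoS2) nanopores. Provides a generative
    model of ionic-current recordings built from per-amino-acid blockade
    statistics (open-pore baseline, Gaussian or two-component mixture
    relative blockades, lognormal dwell times, Poisson arrivals, 10 kHz
    acquisition filtering at 100 kHz sampling), a Transalyzer-style event
    detector (zero-phase Butterworth filtering, moving-average baseline,
    dual-threshold event calling, dwell filtering), kernel-density and
    Gaussian-mixture peak calling of relative current blockades, two-sample
    z-tests, and per-event classifiers: a transparent Gaussian-Bayes
    baseline and an LSTM sequence network with confusion-matrix evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
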