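Package: oscmotifs
Title: Oscillatory Signatures of Spiking Circuit Motifs with Two Interneuron Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates spiking circuits of regular-spiking (pyramidal-like),
    fast-spiking (PV-like) and low-threshold-spiking (SOM-like) Izhikevich
    point neurons across the 20 connectivity motifs that arise from the
    possible SOM wiring and input regimes. Provides the accompanying analysis
    suite: multitaper LFP spectra and band peaks, phase-amplitude coupling via
    the weighted phase-locking factor, per-type firing rates, burst fractions,
    spike-LFP pairwise phase consistency and circular mean phases, and k-means
    clustering of the resulting feature vectors with Calinski-Harabasz
    selection of the cluster count, so that oscillatory regimes (asynchrony,
    PING, ING, stable beta, theta-nested gamma, theta bursting) can be
    reproduced and explored from configuration alone.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
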