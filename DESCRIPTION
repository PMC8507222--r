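Package: meawave
Title: Spike, Network, Oscillation and Phase-Amplitude Coupling Analysis of
    Multielectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multielectrode array (MEA) recordings of
    neuronal networks such as cerebral organoids: threshold-based spike and
    burst detection, activity filtering, functional connectivity graphs from
    spike-count correlations and overlapping bursts, periodicity of network
    events by autocorrelation and Welch periodogram, narrow-band oscillatory
    power via a synchrosqueezed continuous wavelet transform, band-power
    connectivity, and phase-amplitude coupling quantified by the
    Kullback-Leibler modulation index. Includes a synthetic MEA recording
    simulator with healthy and disease phenotype presets providing ground
    truth for every metric, and HDF5/CSV readers and writers for recordings,
    spike tables, graphs and metric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rhdf5,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
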