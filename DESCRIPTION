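Package: axonmea
Title: Spike Detection and Axonal Conduction-Speed Analysis for Microchannel MEA Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of axon bundles
    confined in PDMS microchannels over microelectrode arrays: zero-phase
    Butterworth high-pass filtering, MAD-based noise estimation, 5-sigma
    negative-peak spike detection with a 3 ms dead time, spike-triggered
    time histograms (STTH) and conduction-speed estimation from latency
    peaks, per-channel mean firing rates with Kruskal-Wallis comparisons,
    and axon-length / tunnel-penetration morphometric summaries. Includes
    a seeded synthetic-recording generator that provides ground truth
    (Poisson spike trains, fixed-speed propagation, biphasic waveforms,
    Gaussian noise) for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
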