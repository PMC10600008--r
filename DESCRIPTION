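Package: habtrap
Title: Burst Firing, Synaptic Current and NMDAR Trapping-Block Analysis
    for Habenular Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for the electrophysiology of use-dependent
    NMDA-receptor channel block in the lateral habenula (LHb). Implements
    inter-spike-interval burst detection with the max-interval criteria
    (20 ms onset / 50 ms continuation), binned z-score classification of
    in vivo unit responses to drug injection, evoked-EPSC component
    analysis (AMPAR peak at -70 mV, NMDAR amplitude 35 ms post-stimulus
    at +40 mV, NMDA/AMPA ratios, input-output curves), washout
    normalization with maximal-blockade and recovery statistics,
    mono-exponential pharmacokinetic half-life estimation, and a
    four-state kinetic simulator of open-channel block with trapping
    (closed, open, open-blocked, closed-blocked) driven by stimulation
    protocols. A synthetic-data module generates spike trains, session
    recordings, eEPSC sweeps, washout series and concentration decay
    curves with the statistical structure these analyses assume, so the
    full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
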