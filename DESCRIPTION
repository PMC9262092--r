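Package: e4tools
Title: Signal Analysis for Empatica E4 Wearable Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing physiological recordings from the Empatica
    E4 wristband. Reads and writes session archives in the E4 zip/CSV
    dialect, preprocesses electrodermal activity (upsampling and zero-phase
    FIR low-pass filtering), screens 5-second epochs for artifacts, detects
    skin-conductance-response peaks and their features (amplitude, rise
    time, decay time, width, area under the curve), filters inter-beat
    intervals with physiological plausibility rules, computes time- and
    frequency-domain heart-rate variability, summarizes movement and
    temperature, synchronizes calendar annotations and event tags with
    session time, cuts sessions into fixed-width bins, batch-processes
    folders of archives, and renders self-contained HTML summary reports.
    A seeded synthetic-session generator produces archives with ground
    truth for every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    zoo,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    optparse
Config/testthat/edition: 3
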