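Package: eegfbn
Title: Phase-Synchronization Screening and Functional Brain Networks from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing functional brain networks from multichannel
    EEG by phase synchronization. Implements analytic-signal phase extraction
    (Hilbert transform), the phase-locking value (PLV), the phase lag index
    (PLI) and the weighted phase lag index (wPLI); PLV-based phase-locking
    screening of non-overlapping sliding windows on core electrode pairs
    (Fz-Cz, Fz-Pz); Welch power spectral density estimation with per-region
    band-power summaries; and wPLI connectivity matrices binarized into graphs
    with per-region node-degree statistics and paired comparisons across
    standing-balance paradigms. A synthetic 19-channel generator with planted,
    randomly timed coupling events and a zero-lag common-source mixing stage
    (emulating volume conduction) makes every stage testable without human
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
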