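Package: lsltiming
Title: Timing Simulation and Latency Analysis for Multi-Stream EEG and
    Audio Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the temporal alignment of audio and EEG data
    streams recorded on independent device clocks, as in Lab-Streaming-Layer
    (LSL) style mobile EEG and hearing-device setups.  Provides a simulator of
    a complete two-device recording session (drifting clocks, rectangular
    stimulus pulses with software event markers, an EEG acquisition chain with
    a stochastic sampling schedule, and periodic NTP-style clock-offset
    measurements), readers and writers for a self-contained bundle format and
    a minimal XDF importer, timeline mapping via most-recent-offset or robust
    (Theil-Sen) linear fits, rising-edge detection, ERP-style epoching with
    half-maximum latency extraction, lag/jitter/across-session-range
    summaries, latency-drift fitting, and comparison of clock-offset records
    from two recorders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
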