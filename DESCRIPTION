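Package: rtpeth
Title: Real-Time Peri-Event Time Histograms for Streaming Extracellular Recordings
Version: 0.1.0
Authors@R: person("rtpeth", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Headless toolkit for online peri-event time histogram (PETH)
    analysis of streaming multichannel extracellular recordings: a
    JSON-lines wire format with file replay, a circular sample buffer
    with event-aligned region-of-interest extraction, threshold-crossing
    spike detection with holdoff censoring, per-channel and per-tetrode
    histogram accumulation, and the matching offline validation chain
    (zero-phase Butterworth band-pass filtering, tetrode-wide spike
    merging with largest-spike censoring, online/offline concordance and
    experiment-time accounting). A bundled simulator generates synthetic
    recordings with ground-truth spike, artifact and TTL event times so
    the full online and offline pipelines can be exercised end-to-end
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
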