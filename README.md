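# rtpeth — real-time peri-event time histograms for streaming extracellular recordings

`rtpeth` is a headless R toolkit for *online* peri-event time histogram
(PETH) analysis during extracellular electrophysiology. Its audience is
systems-neuroscience labs doing optogenetic tagging or behavioral
recordings: during a session, a real-time PETH aligned to laser or
reinforcement TTLs tells the experimenter immediately whether the
current electrode position sees short-latency light-evoked units or
behaviorally responsive cells — enabling a systematic "hunt" for neurons
of interest instead of recording every position and finding out offline.

The core statistic: for spikes $\{s_i\}$ and events $\{e_j\}$ on one
sample clock, the PETH with bin width $\Delta$ counts pairs by relative
time,

$$N_k = \#\{(i,j) : s_i - e_j \in [k\Delta, (k+1)\Delta)\},$$

which is the cross-correlation of the two point processes. The package
implements both the streaming formulation (event-aligned windows,
per-window threshold detection with holdoff censoring, incremental
accumulation) and the offline formulation (zero-phase 600–6000 Hz
Butterworth filtering, tetrode-wide spike merging with largest-spike
censoring, binary cross-correlation at 1 ms), plus the validation
arithmetic that compares the two: online/offline concordance
(sensitivity/specificity over tetrode recordings) and experiment-time
accounting. A bundled simulator generates multichannel recordings with
ground-truth spike, photostimulation-artifact and TTL times, so the
whole chain is testable without hardware.

## Worked example

Simulate a 10 s tagging block (20 Hz laser pulses, 2 s ON / 3 s OFF; a
tagged unit on four tetrode wires with evoked probability 0.8 at
3 ± 0.5 ms latency), stream it through the online chain, and judge the
histogram:

```r
library(rtpeth)

rec <- simulate_recording(simulation_config(
  duration_s = 10, n_channels = 4, noise_sd = 20,
  units = list(unit_spec(1:4, gains = c(1, 0.8, 0.65, 0.5),
                         background_rate_hz = 5,
                         evoked = list(probability = 0.8, latency_ms = 3,
                                       jitter_ms = 0.5))),
  stimulus = stimulus_spec(), seed = 7))

res  <- run_online(as_packets(rec), threshold_config(4, -80))
crit <- light_response_criterion(res$peth)

res$n_windows                       # 79  (80 pulses; the t=0 pulse is stale)
nrow(res$spikes)                    # 248 detections across windows
crit$outcome                        # "positive"
crit$score                          # 42.4  (peak vs baseline, z-like)
crit$peak_bin_ms                    # 2     (peak bin [2,3) ms after the pulse)

group_counts(res$peth, grouping_config(4))[, 19:28]
#     -2 -1  0  1  2  3  4  5  6  7   <- bin lower edges, ms
# 1-4  0  0  1  4 72 72 12  0  2  2
```

The tetrode-aggregated histogram is flat before the pulse and piles 144
of 248 detections into the 2–4 ms bins — the short-latency signature the
criterion flags (score 42.4, far above the 3-SD cutoff).

Concordance and time accounting reproduce their printed-table
arithmetic from the bundled CSVs:

```r
counts <- read_session_counts(system.file(
  "extdata", "session_concordance_counts.csv", package = "rtpeth"))
concordance(expand_session_counts(counts))
# Online vs offline light-response concordance
#   TP 37  FP 9  FN 2  TN 96  (n = 144)
#   sensitivity: 94.87%  specificity: 91.43%

d <- read.csv(system.file("extdata", "experiment_durations.csv",
                          package = "rtpeth"))
time_savings(time_budget(nrow(d), d$hours))
# Experiment-time accounting
#   baseline: 90.00 h (7.50 h/animal)
#   actual:   58.50 h  -> recording saved 31.50 h
#   sessions avoided: 42  -> analysis saved 21.00 h
#   total saved: 52.50 h
```

Sensitivity is the true-positive rate of online detection against the
offline reference, `100·TP/(TP+FN)`; the time report compares the
exhaustive protocol (10 positions/animal at 30 min settling + 15 min
recording, 30 min analysis per recorded session) against the measured
per-animal hours.

## Command line

```sh
inst/cli/rtpeth simulate --seed 1 --duration 10 --out stream.jsonl --truth-prefix truth
inst/cli/rtpeth detect   --stream stream.jsonl --threshold -80 --out spikes.csv
inst/cli/rtpeth peth     --spikes spikes.csv --events truth_events.csv --out peth.csv
inst/cli/rtpeth validate --seed 1 --out-prefix val
inst/cli/rtpeth timesave --durations inst/extdata/experiment_durations.csv
```

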