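---
title: "Online peri-event time histograms: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online peri-event time histograms: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpeth)
```

## The problem

During an extracellular recording session the experimenter has to decide,
electrode position by electrode position, whether the wires currently see
neurons worth recording: cells that fire at short latency after laser
pulses (optogenetically tagged members of a genetically defined
population) or cells that respond to behavioral events such as reward or
punishment. Offline analysis answers this days later; an *online*
peri-event time histogram answers it during the session, which is what
makes "hunting" for responsive positions possible and saves a large
fraction of otherwise wasted settling and recording time.

The peri-event time histogram (PETH) of a spike train $\{s_i\}$ against
events $\{e_j\}$ with bin width $\Delta$ counts, for each lag bin
$[k\Delta, (k+1)\Delta)$, the pairs with $s_i - e_j$ in that bin. It is
the cross-correlation of the two point processes, which is also exactly
how this package computes its offline variant.

## The online chain

Packets of continuous voltage samples and TTL events arrive on a single
sample clock (0-based sample counts since acquisition start; 30 kS/s by
default). The `collector()` keeps a ring buffer of recent history
(default 10 s — the stream itself is unbounded) and holds each rising
trigger edge until the buffer covers the full region of interest (ROI,
default 20 ms before to 50 ms after the event). Each aligned window is
then spike-detected independently:

* a detection opens when the voltage *strictly* crosses the threshold
  (falls below it, for the default negative polarity — raw extracellular
  spikes are negative-going). Strict comparison avoids chattering on
  exactly-threshold plateaus;
* the extremum of the supra-threshold run is the peak (earliest sample
  on ties, for determinism); an excursion still open at the window end
  is closed there and counted — dropping it would lose late-window
  spikes;
* after a detection, no new one is accepted until the signal has
  re-crossed the threshold *and* a holdoff dead time (default 0.75 ms, a
  conventional censoring period) has elapsed since the peak.

Consecutive trigger ROIs may overlap; the same spike is then reported
under both events, deliberately. Online accumulation never deduplicates
— that is the offline chain's job — and the repeat-detection behavior is
asserted by a test, not merely tolerated.

Relative spike times are accumulated into half-open bins $[lo, hi)$ so a
spike exactly at the event time lands in $[0, 1)$ ms and no edge is
counted twice. Counts are raw; `peth_rate()` converts to spikes/s/event
for display.

## The offline chain and why it differs

Offline, the luxury of non-causality is available: `bandpass_filter()`
applies a 4th-order Butterworth band-pass (600–6000 Hz) forward and
backward, giving zero phase shift and the squared magnitude response.
No DSP package is assumed: the design is the textbook chain (analog
prototype poles, low-pass-to-band-pass transform with prewarped edges,
bilinear transform), and the tests check it against the closed-form
Butterworth magnitude response — `bandpass_gain()` — rather than against
frozen coefficients.

A single action potential appears on several tetrode wires at different
amplitudes, so per-wire detection counts it repeatedly.
`merge_and_censor()` merges all wires and keeps, within any censoring
window (default 0.75 ms, shared with the online holdoff so counts
compare directly), only the detection with the largest absolute
amplitude — greedy by amplitude, ties broken by earlier time then lower
channel. On simulated tetrodes with per-wire gain variation this
recovers more unique true spikes than any single wire, the qualitative
effect that motivates tetrode-wide censoring.

The offline PETH is computed as a binary cross-correlation: both point
processes are binarized at 1 ms (a bin is 1 if at least one point falls
in it) and the lag histogram counts bin pairs. **Exactness caveat**:
this coincides bin-for-bin with event-loop accumulation iff (i) event
times sit on the resolution grid, (ii) no two events share a bin, and
(iii) no two spikes share a bin. TTL pulse trains at 30 kS/s satisfy
(i)–(ii) by construction (a 20 Hz train steps in 1500-sample = 50 ms
increments) and refractory spiking satisfies (iii). The package also
performs the binning in the integer sample domain whenever a bin is a
whole number of samples; converting sample counts to fractional
milliseconds first makes `floor()` fragile for spikes sitting exactly on
a bin edge, and that wobble is what the integer path eliminates.

## The automated light-response criterion

The original online judgment was the experimenter's; this package
substitutes an explicit rule so that online/offline concordance is
computable: a histogram is *positive* when the maximum count in the
short-latency window (default 0–10 ms) exceeds the pre-event baseline
mean by more than 3 baseline standard deviations, with at least 10
events accumulated (`"insufficient"` otherwise, which is neither
positive nor negative). The 3-SD threshold and the 0–10 ms window are
package choices, not claims inherited from any reference analysis.

Two statistical properties of this rule matter in practice and shaped
the defaults elsewhere:

* **Sparse bins**: with only tens of events, 1 ms baseline bins hold
  ~0.5 counts; `mean + 3·SD` then sits below 3 counts and any chance
  triple in the latency window fires the rule. Stated worlds should
  therefore resemble real tagging blocks: the synthetic concordance
  study (`synthetic_validation()`) uses 25 s sessions (200 pulses;
  real tagging blocks of ~2 min deliver ~960), and the behavioral tests
  use 5 ms bins, matched to the ~10 ms spread of a response at
  20 ± 5 ms latency.
* **Multiplicity**: the rule takes a maximum over latency bins, so its
  false-positive rate is roughly `n_bins x P(count > mean + 3 SD)` — a
  few percent, irreducible without changing the stated rule. Seeded
  stochastic tests account for this.

## The simulator: what it states and what it omits

`simulate_recording()` is a stated world, not a tuning knob:

| parameter | default | why |
|---|---|---|
| sampling rate | 30 kS/s | standard acquisition rate |
| noise | white Gaussian, SD 20 µV | typical spike-band noise floor |
| spike template | biphasic, 1.3 ms, peak −100 µV | conventional extracellular waveform |
| artifact template | W-shaped, 2 ms, −150 µV at intensity 1 | photoelectric transient locked to pulse onset |
| stimulus | 1 ms pulses, 20 Hz, 2 s ON / 3 s OFF | standard tagging protocol |
| evoked response | p = 0.8 per pulse, 3 ± 0.5 ms latency | short-latency opsin-driven spiking |
| refractory period | 2 ms per unit | real units are refractory; also realizes the "gaps > holdoff" premise of the recovery tests |

Spikes are all-or-none: their amplitude never depends on stimulation
intensity. The artifact scales linearly with intensity and is zero at
intensity 0. This dissociation — artifact amplitude halves when
intensity halves while evoked spikes do not move — is the discrimination
logic the end-to-end test asserts. Evoked spikes suppress the unit's
background process around them so ground-truth counting stays
unambiguous; spikes whose template would cross a recording edge are
dropped from the ground truth; the finished signal is quantized to
float32 (the wire and recording precision), which is why streaming and
replay reproduce it *bit-exactly*. Every output is a pure function of
(config, seed).

Deliberate omissions: no 1/f or line noise, no electrode drift, no
overlapping-unit waveform superposition beyond linear summation, no
population spikes. A green test on this world therefore establishes the
correctness of the *computational chain*, not robustness to every
failure mode of in vivo data.

## Numerical choices

* ms→samples conversion rounds half away from zero, applied once per
  boundary, never cumulatively — window lengths cannot drift by one
  sample and do not depend on tie parity.
* An event becomes ready when the buffer end reaches `event + post`
  (one sample conservative), and the aligned window is
  `[event − pre, event + post)` with `t0_offset = pre` (0-based).
* Buffer gaps (dropped packets) are zero-filled with a warning; a live
  stream must not abort analysis. Stale events (window precedes retained
  history) are skipped and counted, not fatal.
* Filtering pads with odd reflection sized from the slowest pole of the
  design (transients decay below 1e-8 inside the padding).
* Sensitivity/specificity are computed in full precision and printed to
  two decimals; with no positive (or no negative) reference records the
  corresponding rate is `undefined`, never silently 0.
* Sessions actually recorded are recovered as
  `actual_hours / (settle + record)` and rounded to the nearest whole
  session before computing sessions avoided.

## Detection recovery: the stated operating point

The recovery tests run at SNR 5 (template peak −100 µV, noise SD 20 µV)
with the threshold at −4 noise SD. At 30 kS/s, white noise alone crosses
−4 SD about once per second regardless of how many spikes there are, so
the "false positives per true spike" bound is only meaningful at
realistic *multiunit* rates; the tests use 40 Hz, the scale of unsorted
activity on one tetrode wire, which is what online detection actually
sees. The threshold-sweep monotonicity property (sensitivity
non-increasing in |threshold|) is tested where false-crossing censoring
is negligible; at −2 SD thresholds the holdoff windows opened by noise
crossings start censoring true spikes, a real effect that genuinely
breaks monotonicity.

## Known limitations

* The light-response criterion is a surrogate for human judgment and for
  published latency-test statistics; its concordance numbers on
  synthetic data are an analogue, not a reproduction, of any real
  study's table.
* The live transport adapter is out of scope by design: every
  computation runs transport-free from JSON-lines files, and the
  heartbeat contract is modeled but carries no asserted timing.
* GUI rendering is replaced by CSV outputs (`cli_main()` subcommands
  `simulate`, `detect`, `peth`, `validate`, `timesave`).
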