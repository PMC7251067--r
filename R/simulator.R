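# Synthetic extracellular recordings with ground truth. The generator
# states a world consistent with in vivo tagging sessions: 30 kS/s
# multichannel data, white Gaussian background noise, all-or-none
# biphasic unit spikes whose amplitude never depends on light intensity,
# W-shaped photostimulation artifacts locked to pulse onset whose
# amplitude scales linearly with intensity, and 1 ms laser pulses at
# 20 Hz in a 2 s ON / 3 s OFF duty cycle. Every output is a pure
# function of (config, seed).

#' Biphasic extracellular spike template
#'
#' Negative main phase with a smaller positive rebound, 1.3 ms support.
#' Amplitude is fixed per unit (all-or-none): an action potential does
#' not scale with stimulation intensity.
#'
#' @param sampling_rate samples per second.
#' @param peak_uv main-phase peak, microvolts (negative; default -100).
#' @return numeric vector of template samples, microvolts.
#' @export
spike_template <- function(sampling_rate = 30000, peak_uv = -100) {
  t_ms <- seq(0, 1.3, by = 1000 / sampling_rate)
  w <- -exp(-((t_ms - 0.35) / 0.10)^2) + 0.30 * exp(-((t_ms - 0.80) / 0.25)^2)
  w * (peak_uv / min(w))
}

#' W-shaped photostimulation artifact template
#'
#' Two negative lobes over 2 ms, locked to the pulse onset. Unlike
#' spikes, the inserted artifact amplitude scales linearly with the
#' stimulation intensity; the bimodal shape produces the characteristic
#' double-peaked histogram photoelectric artifacts leave in a PETH.
#'
#' @param sampling_rate samples per second.
#' @param peak_uv lobe peak at full intensity, microvolts (default -150).
#' @return numeric vector of template samples, microvolts.
#' @export
artifact_template <- function(sampling_rate = 30000, peak_uv = -150) {
  t_ms <- seq(0, 2, by = 1000 / sampling_rate)
  w <- -exp(-((t_ms - 0.5) / 0.18)^2) - 0.9 * exp(-((t_ms - 1.4) / 0.22)^2)
  w * (peak_uv / min(w))
}

#' Specification of one simulated unit
#'
#' @param channels 1-based channel ids the unit appears on.
#' @param gains per-channel amplitude gain (recycled; a real neuron's
#'   spike shows with different amplitudes on different tetrode wires).
#' @param background_rate_hz spontaneous Poisson rate.
#' @param evoked `NULL` for an untagged unit, else a list with
#'   `probability` (per pulse, in `[0,1]`), `latency_ms`, `jitter_ms`
#'   (Gaussian SD), and optionally `event_channel` (digital line whose
#'   events evoke spikes; defaults to the stimulus TTL channel).
#' @param refractory_ms minimum inter-spike interval (default 2 ms, a
#'   typical absolute-plus-relative refractory period); the ground-truth
#'   train is thinned to honor it, which keeps ground-truth counting
#'   compatible with detection censoring.
#' @param template spike waveform (default [spike_template()] at -100 uV).
#' @return object of class `unit_spec`.
#' @export
unit_spec <- function(channels, gains = 1, background_rate_hz = 5,
                      evoked = NULL, refractory_ms = 2, template = NULL) {
  if (!is.null(evoked)) {
    if (is.null(evoked$jitter_ms)) evoked$jitter_ms <- 0
    stopifnot(evoked$probability >= 0, evoked$probability <= 1,
              evoked$jitter_ms >= 0)
  }
  stopifnot(refractory_ms >= 0)
  structure(list(channels = as.integer(channels),
                 gains = rep_len(gains, length(channels)),
                 background_rate_hz = background_rate_hz,
                 evoked = evoked, refractory_ms = refractory_ms,
                 template = template),
            class = "unit_spec")
}

#' Specification of the photostimulation artifact
#'
#' @param channels 1-based channel ids affected.
#' @param intensity stimulation intensity in arbitrary units `[0, 1]`;
#'   the inserted artifact amplitude is `intensity * template`, so
#'   intensity 0 yields no artifact at all.
#' @param template artifact waveform at full intensity (default
#'   [artifact_template()]).
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(channels, intensity = 1, template = NULL) {
  stopifnot(intensity >= 0, intensity <= 1)
  structure(list(channels = as.integer(channels), intensity = intensity,
                 template = template),
            class = "artifact_spec")
}

#' Photostimulation pulse-train specification
#'
#' Defaults mirror a standard optogenetic tagging protocol: 1 ms square
#' pulses at 20 Hz with a 2 s ON / 3 s OFF duty cycle.
#'
#' @param pulse_rate_hz pulses per second during ON epochs.
#' @param pulse_width_ms TTL pulse width (metadata; onsets drive the PETH).
#' @param on_s,off_s epoch durations, seconds; `pulse_rate_hz * on_s`
#'   must be a whole pulse count.
#' @param event_channel digital line carrying the pulse TTLs (default 1).
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(pulse_rate_hz = 20, pulse_width_ms = 1,
                          on_s = 2, off_s = 3, event_channel = 1) {
  n_pulses <- pulse_rate_hz * on_s
  if (abs(n_pulses - round(n_pulses)) > 1e-9)
    stop_field("on_s", "pulse_rate_hz * on_s must be an integral pulse count")
  structure(list(pulse_rate_hz = pulse_rate_hz,
                 pulse_width_ms = pulse_width_ms,
                 on_s = on_s, off_s = off_s,
                 event_channel = as.integer(event_channel)),
            class = "stimulus_spec")
}

#' Pulse-onset timestamps of a duty-cycled stimulus train
#'
#' Epochs alternate ON then OFF starting at t = 0; pulses fire at the
#' pulse rate during ON epochs only. Deterministic (no randomness).
#'
#' @param spec a [stimulus_spec()].
#' @param duration_s total duration covered.
#' @param sampling_rate samples per second.
#' @return numeric vector of pulse-onset timestamps in samples (0-based),
#'   strictly inside `[0, duration_s)`.
#' @export
generate_stimulus_train <- function(spec, duration_s,
                                    sampling_rate = 30000) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$on_s == 0) return(numeric(0))
  cycle <- spec$on_s + spec$off_s
  starts <- seq(0, duration_s, by = cycle)
  within_on <- (seq_len(round(spec$pulse_rate_hz * spec$on_s)) - 1) /
    spec$pulse_rate_hz
  t <- as.vector(outer(within_on, starts, "+"))
  t <- sort(t[t < duration_s])
  round(t * sampling_rate)
}

#' Full simulation configuration
#'
#' @param duration_s recording length, seconds.
#' @param n_channels number of continuous channels (default 4, a tetrode).
#' @param sampling_rate samples per second (default 30000).
#' @param noise_sd white Gaussian background noise SD, microvolts
#'   (default 20, a typical in vivo spike-band noise floor).
#' @param units list of [unit_spec()]s.
#' @param artifact an [artifact_spec()] or `NULL`.
#' @param stimulus a [stimulus_spec()] or `NULL`.
#' @param extra_events data.frame (`channel`, `timestamp`) of additional
#'   TTL events (behavioral reward/punishment lines), or `NULL`.
#' @param seed mandatory integer seed; identical (config, seed) gives
#'   bit-identical output.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s, n_channels = 4,
                              sampling_rate = 30000, noise_sd = 20,
                              units = list(), artifact = NULL,
                              stimulus = NULL, extra_events = NULL,
                              seed) {
  if (missing(seed) || !is_count(seed, positive = FALSE))
    stop_field("seed", "an integer seed is mandatory")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_field("duration_s", "must be > 0")
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  structure(list(duration_s = duration_s, n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 units = units, artifact = artifact, stimulus = stimulus,
                 extra_events = extra_events, seed = as.integer(seed)),
            class = "simulation_config")
}

# quantize to float32 so that streaming (float32 payload) round-trips
# bit-exactly; this is also the realistic acquisition precision
quantize_f32 <- function(x) {
  dim_x <- dim(x)
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               numeric(), n = length(x), size = 4L, endian = "little")
  dim(q) <- dim_x
  q
}

# 1-based signal columns covering a template whose extremum (or first
# sample, for onset-locked artifacts) sits at 0-based sample ts;
# NULL when the template does not fit inside the recording
template_cols <- function(ts, template, n_total, align_peak = TRUE) {
  peak_at <- if (align_peak) which.max(abs(template)) else 1L
  start <- ts - (peak_at - 1L)              # 0-based
  if (start < 0 || start + length(template) > n_total) return(NULL)
  start + seq_along(template)               # 1-based columns
}

#' Simulate a multichannel extracellular recording with ground truth
#'
#' Signal = white Gaussian noise + unit templates inserted at
#' ground-truth spike times (per-channel gains) + the artifact waveform
#' at every stimulus pulse, scaled linearly by intensity. Overlapping
#' insertions are summed, never an error. Evoked spikes suppress the
#' unit's own background process within +-1 ms so ground-truth counting
#' stays unambiguous; spikes whose template would cross a recording edge
#' are dropped from the ground truth. The finished signal is quantized to
#' float32 (the wire/recording precision), so streaming and replay
#' reproduce it bit-exactly.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_recording`: `signal`
#'   (`[channel, sample]`, microvolts), `sampling_rate`, `events`
#'   (data.frame `channel`, `timestamp` of every TTL), and
#'   `ground_truth` (per-unit data.frames `timestamp`, `kind`
#'   (`"spontaneous"`/`"evoked"`), plus `artifact_onsets`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  signal <- matrix(stats::rnorm(config$n_channels * n, 0, config$noise_sd),
                   nrow = config$n_channels)

  events <- data.frame(channel = integer(), timestamp = numeric())
  pulses <- numeric(0)
  if (!is.null(config$stimulus)) {
    pulses <- generate_stimulus_train(config$stimulus, config$duration_s, fs)
    events <- rbind(events, data.frame(channel = config$stimulus$event_channel,
                                       timestamp = pulses))
  }
  if (!is.null(config$extra_events))
    events <- rbind(events, config$extra_events[c("channel", "timestamp")])
  events <- events[order(events$timestamp, events$channel), , drop = FALSE]
  rownames(events) <- NULL

  unit_truth <- vector("list", length(config$units))
  for (u in seq_along(config$units)) {
    spec <- config$units[[u]]
    template <- spec$template
    if (is.null(template)) template <- spike_template(fs)
    ev_times <- numeric(0)
    if (!is.null(spec$evoked)) {
      ch <- spec$evoked$event_channel
      if (is.null(ch)) ch <- if (!is.null(config$stimulus))
        config$stimulus$event_channel else 1L
      trig <- events$timestamp[events$channel == ch]
      fire <- stats::runif(length(trig)) < spec$evoked$probability
      lat <- spec$evoked$latency_ms +
        spec$evoked$jitter_ms * stats::rnorm(sum(fire))
      ev_times <- round(trig[fire] + lat / 1000 * fs)
    }
    n_spont <- stats::rpois(1, spec$background_rate_hz * config$duration_s)
    sp_times <- round(sort(stats::runif(n_spont, 0, n - 1)))
    if (length(ev_times) && length(sp_times)) {
      # evoked spikes take precedence: suppress the background process
      # around them (at least +-1 ms, widened to the refractory period)
      guard <- ms_to_samples(max(1, spec$refractory_ms), fs)
      near <- vapply(sp_times, function(t)
        any(abs(t - ev_times) <= guard), logical(1))
      sp_times <- sp_times[!near]
    }
    truth <- data.frame(
      timestamp = c(ev_times, sp_times),
      kind = rep(c("evoked", "spontaneous"),
                 c(length(ev_times), length(sp_times))))
    truth <- truth[order(truth$timestamp), , drop = FALSE]
    if (spec$refractory_ms > 0 && nrow(truth) > 1) {
      # sequential thinning: a spike inside the previous kept spike's
      # refractory period never happens
      refr <- ms_to_samples(spec$refractory_ms, fs)
      keep <- logical(nrow(truth)); last <- -Inf
      for (i in seq_len(nrow(truth))) {
        if (truth$timestamp[i] - last >= refr) {
          keep[i] <- TRUE; last <- truth$timestamp[i]
        }
      }
      truth <- truth[keep, , drop = FALSE]
    }
    inserted <- logical(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      cols <- template_cols(truth$timestamp[i], template, ncol(signal))
      if (is.null(cols)) next
      for (k in seq_along(spec$channels))
        signal[spec$channels[k], cols] <- signal[spec$channels[k], cols] +
          spec$gains[k] * template
      inserted[i] <- TRUE
    }
    truth <- truth[inserted, , drop = FALSE]
    rownames(truth) <- NULL
    unit_truth[[u]] <- truth
  }

  artifact_onsets <- numeric(0)
  if (!is.null(config$artifact) && config$artifact$intensity > 0 &&
      length(pulses)) {
    template <- config$artifact$template
    if (is.null(template)) template <- artifact_template(fs)
    wave <- template * config$artifact$intensity
    for (t in pulses) {
      cols <- template_cols(t, wave, ncol(signal), align_peak = FALSE)
      if (is.null(cols)) next
      for (ch in config$artifact$channels)
        signal[ch, cols] <- signal[ch, cols] + wave
      artifact_onsets <- c(artifact_onsets, t)
    }
  }

  structure(
    list(signal = quantize_f32(signal), sampling_rate = fs,
         duration_s = config$duration_s, events = events,
         ground_truth = list(units = unit_truth,
                             artifact_onsets = artifact_onsets),
         config = config),
    class = "simulated_recording")
}

#' Write a simulated recording as a JSON-lines stream file
#'
#' Sample packets tile the recording exactly (the last packet may be
#' short); TTL events are interleaved immediately before the sample
#' packet whose span contains their timestamp, as on a live stream.
#' Replaying the file reproduces the signal matrix bit-exactly.
#'
#' @param recording a [simulate_recording()] result.
#' @param path output file path.
#' @param packet_samples samples per packet (default 640).
#' @param include_events include TTL event lines (default `TRUE`).
#' @return `path`, invisibly.
#' @export
stream_packets <- function(recording, path, packet_samples = 640,
                           include_events = TRUE) {
  stopifnot(inherits(recording, "simulated_recording"), packet_samples >= 1)
  n <- ncol(recording$signal)
  ev <- if (include_events) recording$events else
    data.frame(channel = integer(), timestamp = numeric())
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  ei <- 1L
  con <- file(path, open = "wt")
  on.exit(close(con))
  start <- 0
  while (start < n) {
    len <- min(packet_samples, n - start)
    while (ei <= nrow(ev) && ev$timestamp[ei] < start + len) {
      writeLines(encode_packet(trigger_event(ev$channel[ei],
                                             ev$timestamp[ei])), con)
      ei <- ei + 1L
    }
    pk <- sample_packet(start,
                        recording$signal[, (start + 1):(start + len),
                                         drop = FALSE],
                        recording$sampling_rate)
    writeLines(encode_packet(pk), con)
    start <- start + len
  }
  while (ei <= nrow(ev)) {
    writeLines(encode_packet(trigger_event(ev$channel[ei],
                                           ev$timestamp[ei])), con)
    ei <- ei + 1L
  }
  invisible(path)
}

#' Simulate a behavioral session with reward and punishment TTLs
#'
#' Two digital lines mark reinforcement delivery (reward on channel 2,
#' punishment on channel 3 by default); a configured unit responds after
#' one label only, with the stated probability and latency, while firing
#' at its background rate otherwise. Ground truth marks responsive
#' trials, so online detection of the selective response can be checked
#' against construction.
#'
#' @param n_trials number of trials.
#' @param iti_s inter-trial interval, seconds (default 1.5).
#' @param response list: `label` (`"punishment"` or `"reward"`; `"none"`
#'   for an unresponsive control unit), `probability`, `latency_ms`,
#'   `jitter_ms`.
#' @param n_channels,noise_sd,sampling_rate as in [simulation_config()].
#' @param background_rate_hz unit's spontaneous rate (default 5 Hz).
#' @param seed mandatory integer seed.
#' @return a `simulated_recording` whose `trials` field is a data.frame
#'   (`trial`, `label`, `timestamp`); reward TTLs on channel 2,
#'   punishment on channel 3.
#' @export
generate_behavioral_session <- function(n_trials, iti_s = 1.5,
                                        response = list(label = "punishment",
                                                        probability = 0.9,
                                                        latency_ms = 20,
                                                        jitter_ms = 5),
                                        n_channels = 2, noise_sd = 20,
                                        sampling_rate = 30000,
                                        background_rate_hz = 5, seed) {
  stopifnot(n_trials > 0)
  if (missing(seed)) stop_field("seed", "an integer seed is mandatory")
  set.seed(seed)
  labels <- sample(c("reward", "punishment"), n_trials, replace = TRUE)
  t_s <- 0.5 + (seq_len(n_trials) - 1) * iti_s
  duration_s <- max(t_s) + iti_s
  chan <- ifelse(labels == "reward", 2L, 3L)
  extra <- data.frame(channel = chan,
                      timestamp = round(t_s * sampling_rate))
  evoked <- NULL
  if (!identical(response$label, "none"))
    evoked <- list(probability = response$probability,
                   latency_ms = response$latency_ms,
                   jitter_ms = response$jitter_ms,
                   event_channel = if (response$label == "reward") 2L else 3L)
  cfg <- simulation_config(
    duration_s = duration_s, n_channels = n_channels,
    sampling_rate = sampling_rate, noise_sd = noise_sd,
    units = list(unit_spec(channels = seq_len(min(n_channels, 2L)),
                           gains = c(1, 0.7)[seq_len(min(n_channels, 2L))],
                           background_rate_hz = background_rate_hz,
                           evoked = evoked)),
    extra_events = extra,
    seed = seed + 1L)
  rec <- simulate_recording(cfg)
  rec$trials <- data.frame(trial = seq_len(n_trials), label = labels,
                           timestamp = extra$timestamp)
  rec
}
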