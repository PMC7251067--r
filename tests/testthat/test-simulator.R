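test_that("stimulus trains follow the ON/OFF duty cycle", {
  spec <- stimulus_spec()   # 20 Hz, 2 s ON / 3 s OFF
  fs <- 30000
  # 10 s = two full cycles -> 2 x 40 pulses
  p10 <- generate_stimulus_train(spec, 10, fs)
  expect_length(p10, 80)
  # 2 s = a single ON epoch
  p2 <- generate_stimulus_train(spec, 2, fs)
  expect_length(p2, 40)
  expect_equal(p2, seq(0, by = 1500, length.out = 40))  # 30000/20 samples
  # pulses only inside ON epochs
  t_s <- p10 / fs
  phase <- t_s %% 5
  expect_true(all(phase < 2))
  # degenerate: no ON time, no pulses
  expect_length(generate_stimulus_train(stimulus_spec(on_s = 0, off_s = 3),
                                        10, fs), 0)
  expect_error(stimulus_spec(pulse_rate_hz = 20, on_s = 0.33), "on_s")
})

test_that("silence in, silence out; identical seeds are bit-identical", {
  quiet <- simulate_recording(simulation_config(
    duration_s = 0.1, n_channels = 2, noise_sd = 0, seed = 1))
  expect_true(all(quiet$signal == 0))

  a <- tiny_tagged_recording(seed = 5, duration_s = 1)
  b <- tiny_tagged_recording(seed = 5, duration_s = 1)
  expect_identical(a$signal, b$signal)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- tiny_tagged_recording(seed = 6, duration_s = 1)
  expect_false(identical(a$signal, c$signal))
  expect_error(simulation_config(duration_s = 1), "seed")
})

test_that("evoked spike counts are binomial and land at the set latency", {
  # 100 pulses at probability 0.8: count within the binomial 99% interval
  rec <- simulate_recording(simulation_config(
    duration_s = 11, n_channels = 1, noise_sd = 0,
    units = list(unit_spec(1, background_rate_hz = 0,
                           evoked = list(probability = 0.8, latency_ms = 3,
                                         jitter_ms = 0.5))),
    stimulus = stimulus_spec(), seed = 11))
  pulses <- rec$events$timestamp[rec$events$channel == 1]
  expect_length(pulses, 100)   # ON epochs at 0, 5, 10 s -> 40 + 40 + 20
  truth <- rec$ground_truth$units[[1]]
  n_evoked <- sum(truth$kind == "evoked")
  expect_gte(n_evoked, qbinom(0.005, length(pulses), 0.8))
  expect_lte(n_evoked, qbinom(0.995, length(pulses), 0.8))
  # evoked spikes lie within latency +- 4 * jitter of their pulse
  rel_ms <- vapply(truth$timestamp[truth$kind == "evoked"], function(t)
    min(abs(t - pulses)) / 30, numeric(1))
  expect_true(all(rel_ms >= 3 - 4 * 0.5 & rel_ms <= 3 + 4 * 0.5))
  # the PETH of ground-truth spikes peaks in [2, 4) ms
  acc <- peth_accumulator(1, 20, 50)
  for (p in pulses)
    acc <- peth_update(acc, data.frame(channel = 1, timestamp = truth$timestamp),
                       trigger_event(1, p), 30000)
  peak_lo <- acc$edges[which.max(acc$counts[1, ])]
  expect_gte(peak_lo, 2); expect_lt(peak_lo, 4)
})

test_that("artifact amplitude scales linearly with intensity, spikes do not", {
  mk <- function(intensity) simulate_recording(simulation_config(
    duration_s = 2, n_channels = 1, noise_sd = 0,
    artifact = artifact_spec(1, intensity = intensity),
    stimulus = stimulus_spec(), seed = 21))
  r100 <- mk(1); r50 <- mk(0.5); r25 <- mk(0.25)
  peak <- function(r) max(abs(r$signal))
  expect_equal(peak(r50) / peak(r100), 0.5, tolerance = 1e-6)
  expect_equal(peak(r25) / peak(r100), 0.25, tolerance = 1e-6)
  r0 <- simulate_recording(simulation_config(
    duration_s = 2, n_channels = 1, noise_sd = 0,
    artifact = artifact_spec(1, intensity = 0),
    stimulus = stimulus_spec(), seed = 21))
  expect_true(all(r0$signal == 0))

  # all-or-none spikes: evoked amplitude identical across intensities
  mk_spk <- function(intensity) simulate_recording(simulation_config(
    duration_s = 2, n_channels = 1, noise_sd = 0,
    units = list(unit_spec(1, background_rate_hz = 0,
                           evoked = list(probability = 1, latency_ms = 10,
                                         jitter_ms = 0))),
    artifact = artifact_spec(1, intensity = intensity),
    stimulus = stimulus_spec(), seed = 22))
  s100 <- mk_spk(1); s50 <- mk_spk(0.5)
  truth <- s100$ground_truth$units[[1]]
  spike_amp <- function(r) abs(r$signal[1, truth$timestamp[5] + 1])
  expect_equal(spike_amp(s100), spike_amp(s50), tolerance = 1e-6)
  expect_equal(spike_amp(s100), 100, tolerance = 1e-4)
})

test_that("packet tiling is exact and events interleave correctly", {
  rec <- tiny_tagged_recording(seed = 31, duration_s = 2, n_channels = 2)
  pk <- as_packets(rec, packet_samples = 640)
  samples <- Filter(function(p) inherits(p, "sample_packet"), pk)
  expect_length(samples, ceiling(60000 / 640))
  expect_equal(samples[[length(samples)]]$n_samples, 60000 %% 640)
  rebuilt <- do.call(cbind, lapply(samples, function(p) p$samples))
  expect_identical(rebuilt, rec$signal)
  # timestamps tile without overlap
  starts <- vapply(samples, function(p) p$start_timestamp, numeric(1))
  lens <- vapply(samples, function(p) p$n_samples, numeric(1))
  expect_equal(starts, cumsum(c(0, head(lens, -1))))
  # every event precedes the end of the packet that covers it
  expect_equal(sum(vapply(pk, inherits, logical(1), "trigger_event")),
               nrow(rec$events))
  expect_length(Filter(function(p) inherits(p, "trigger_event"),
                       as_packets(rec, include_events = FALSE)), 0)
})

test_that("behavioral sessions drive a label-selective response", {
  # 5 ms bins: matched to the ~10 ms spread of a behavioral response at
  # 20 +- 5 ms latency, so the 3-SD criterion is not dominated by the
  # multiplicity of near-empty 1 ms bins
  rec <- generate_behavioral_session(n_trials = 120, seed = 41)
  expect_equal(nrow(rec$trials), 120)
  roi <- roi_window(40, 60)
  res <- run_online(as_packets(rec), threshold_config(2, -80),
                    trigger_channel = 3, roi = roi, bin_width_ms = 5)
  crit_pun <- light_response_criterion(res$peth,
                                       latency_window_ms = c(10, 40))
  expect_equal(crit_pun$outcome, "positive")
  res_rew <- run_online(as_packets(rec), threshold_config(2, -80),
                        trigger_channel = 2, roi = roi, bin_width_ms = 5)
  crit_rew <- light_response_criterion(res_rew$peth,
                                       latency_window_ms = c(10, 40))
  expect_equal(crit_rew$outcome, "negative")

  # unresponsive control: both histograms flat
  rec0 <- generate_behavioral_session(n_trials = 80,
                                      response = list(label = "none"),
                                      seed = 42)
  res0 <- run_online(as_packets(rec0), threshold_config(2, -80),
                     trigger_channel = 3, roi = roi, bin_width_ms = 5)
  expect_equal(light_response_criterion(res0$peth,
                                        latency_window_ms = c(10, 40))$outcome,
               "negative")
})

test_that("a 254-trial session generates at desk scale", {
  t0 <- Sys.time()
  rec <- generate_behavioral_session(n_trials = 254, n_channels = 1,
                                     seed = 51)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_equal(nrow(rec$trials), 254)
  expect_gt(ncol(rec$signal), 254 * 1.5 * 30000 - 30000)
  expect_lt(elapsed, 60)
})

test_that("threshold sweep trades sensitivity monotonically", {
  # noise low enough that false-crossing censoring cannot eat true spikes
  # at the loosest threshold (the idealized monotone trade-off)
  rec <- tiny_tagged_recording(seed = 61, duration_s = 5, noise_sd = 10,
                               n_channels = 1)
  truth <- rec$ground_truth$units[[1]]$timestamp
  sens <- vapply(c(-40, -60, -80, -100, -120), function(thr) {
    d <- detect_continuous(rec$signal, 30000, threshold_config(1, thr))
    sum(vapply(truth, function(t) any(abs(d$timestamp - t) <= 15),
               logical(1))) / length(truth)
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-9))  # non-increasing in |threshold|
})
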