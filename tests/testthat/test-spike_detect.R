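mk_window <- function(x, fs = 30000, start_timestamp = 0) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  list(samples = x, sampling_rate = fs, start_timestamp = start_timestamp)
}

test_that("the crossing/peak rule matches a hand trace", {
  w <- mk_window(c(0, 0, -60, -80, -60, 0))
  d <- detect_spikes(w, threshold_config(1, -50))
  expect_equal(nrow(d), 1)
  expect_equal(d$excursion_start, 3)  # 1-based: samples 3..5 are below
  expect_equal(d$excursion_end, 5)
  expect_equal(d$peak_index, 4)
  expect_equal(d$peak_amplitude, -80)
  expect_equal(d$timestamp, 3)        # absolute, 0-based

  # all-quiet window
  expect_equal(nrow(detect_spikes(mk_window(rep(0, 100)),
                                  threshold_config(1, -50))), 0)

  # excursion still open at the window end is closed and counted
  d2 <- detect_spikes(mk_window(c(0, 0, -60, -90)), threshold_config(1, -50))
  expect_equal(d2$peak_index, 4)
  expect_equal(d2$excursion_end, 4)
})

test_that("holdoff censors close crossings but not distant ones", {
  fs <- 30000
  dip <- function(at_ms) {
    x <- rep(0, 200)
    i <- ms_to_samples(at_ms, fs)
    x[i + 0:2] <- c(-60, -80, -60)
    x
  }
  cfg <- threshold_config(1, -50, holdoff_ms = 0.75)
  # two dips 0.2 ms apart -> second censored
  x <- dip(1) + dip(1.2)
  expect_equal(nrow(detect_spikes(mk_window(x, fs), cfg)), 1)
  # 2 ms apart -> both detected
  x2 <- dip(1) + dip(3)
  expect_equal(nrow(detect_spikes(mk_window(x2, fs), cfg)), 2)
})

test_that("detection matches the naive state-machine oracle on random input", {
  set.seed(21)
  fs <- 30000
  cfg <- threshold_config(1, -50, holdoff_ms = 0.75)
  hold <- ms_to_samples(0.75, fs)
  for (i in 1:25) {
    x <- rnorm(3000, 0, 25)
    d <- detect_spikes(mk_window(x, fs), cfg)
    expect_equal(d$peak_index, oracle_detect(x, -50, hold))
    # censoring invariant: peaks never closer than the holdoff
    if (nrow(d) > 1) expect_true(all(diff(d$peak_index) >= hold))
  }
})

test_that("positive polarity mirrors negative detection", {
  x <- c(0, 0, 60, 80, 60, 0)
  d <- detect_spikes(mk_window(x), threshold_config(1, 50, polarity = "positive"))
  expect_equal(d$peak_index, 4)
  expect_equal(d$peak_amplitude, 80)
})

test_that("detection is translation-equivariant", {
  set.seed(5)
  x <- rnorm(2000, 0, 25)
  cfg <- threshold_config(1, -55)
  d0 <- detect_spikes(mk_window(x), cfg)
  k <- 137
  d1 <- detect_spikes(mk_window(c(rep(0, k), x)), cfg)
  expect_equal(d1$peak_index, d0$peak_index + k)
  expect_equal(d1$peak_amplitude, d0$peak_amplitude)
})

test_that("every inserted template above threshold is found once", {
  # 100 spikes, gaps >> holdoff, SNR-free (no noise): exactly 100 detections
  fs <- 30000
  template <- spike_template(fs, -100)
  x <- rep(0, 100 * 90 + 200)
  truth <- integer(100)
  for (i in 1:100) {
    at <- 50 + (i - 1) * 90   # 3 ms apart
    x[at + seq_along(template) - 1] <- x[at + seq_along(template) - 1] + template
    truth[i] <- at + which.min(template) - 1
  }
  d <- detect_spikes(mk_window(x, fs), threshold_config(1, -50))
  expect_equal(nrow(d), 100)
  expect_equal(d$peak_index, truth)
})

test_that("disabled channels yield no detections", {
  m <- rbind(c(0, -80, 0, 0), c(0, -80, 0, 0))
  cfg <- threshold_config(2, -50, disabled_channels = "2")
  d <- detect_spikes(mk_window(m), cfg)
  expect_equal(unique(d$channel), 1L)
})

test_that("overlapping trigger ROIs report the same spike repeatedly", {
  # one spike, two events whose ROIs both cover it: online mode must NOT
  # deduplicate (the documented repeat-detection behavior)
  fs <- 1000
  x <- rep(0, 300); x[150] <- -80
  buf <- ring_buffer(1, fs, capacity_s = 1)
  append_samples(buf, sample_packet(0, matrix(x, 1, 300), fs))
  roi <- roi_window(50, 60)
  cfg <- threshold_config(1, -50)
  w1 <- extract_roi(buf, trigger_event(1, 140), roi)
  w2 <- extract_roi(buf, trigger_event(1, 160), roi)
  d1 <- detect_spikes(w1, cfg)
  d2 <- detect_spikes(w2, cfg)
  expect_equal(d1$timestamp, 149)
  expect_equal(d2$timestamp, 149)  # same absolute spike, both events
})

test_that("waveform extraction spans -0.3 to +1 ms around the peak", {
  fs <- 30000
  x <- rnorm(300)
  w <- mk_window(x, fs)
  wf <- extract_waveform(list(channel = 1, peak_index = 100), w)
  # 0.3 ms * 30 = 9 samples before, 1.0 ms * 30 = 30 after
  expect_equal(length(wf$samples), ms_to_samples(1.3, fs) + 1)
  expect_identical(wf$samples, x[91:130])
  expect_identical(wf$peak_offset, 9)
  # span exceeding the window: waveform skipped, not an error
  expect_null(extract_waveform(list(channel = 1, peak_index = 3), w))
  expect_null(extract_waveform(list(channel = 1, peak_index = 280), w))
})

test_that("a template spike's waveform is template plus noise", {
  fs <- 30000
  rec <- tiny_tagged_recording(seed = 3, duration_s = 2, noise_sd = 10,
                               n_channels = 1)
  truth <- rec$ground_truth$units[[1]]
  template <- spike_template(fs)
  t0 <- truth$timestamp[5]
  w <- mk_window(rec$signal, fs)
  wf <- extract_waveform(list(channel = 1, peak_index = t0 + 1), w,
                         pre_ms = 0.3, post_ms = 1.0)
  padded <- c(rep(0, 40), template, rep(0, 40))  # template is 0 outside support
  peak_at <- which.min(padded)
  tpl_cut <- padded[(peak_at - 9):(peak_at + 30)]
  resid <- wf$samples - tpl_cut
  expect_lt(max(abs(resid)), 5 * 10)   # residual is noise-sized, not spike-sized
  expect_lt(sd(resid), 2.5 * 10)
})

test_that("channel range notation parses both stated forms", {
  expect_equal(parse_channel_ranges("1, 2, 3"), c(1L, 2L, 3L))
  expect_equal(parse_channel_ranges("1-3"), c(1L, 2L, 3L))
  expect_equal(parse_channel_ranges("1–3"), c(1L, 2L, 3L))  # en dash
  expect_equal(parse_channel_ranges(""), integer(0))
  expect_equal(parse_channel_ranges("2-2"), 2L)
  expect_equal(parse_channel_ranges("1,2,5-7"), c(1L, 2L, 5L, 6L, 7L))
  expect_equal(parse_channel_ranges(" 4 , 1 - 2 "), c(1L, 2L, 4L))
  expect_error(parse_channel_ranges("3-1"), "3-1")
  expect_error(parse_channel_ranges("a"), "'a'")
})

test_that("thresholds adjust per channel or all at once, sign-checked", {
  cfg <- threshold_config(4, -50)
  cfg <- set_threshold(cfg, "all", -60)
  expect_equal(cfg$threshold, rep(-60, 4))
  cfg <- set_threshold(cfg, 3, -80)
  expect_equal(cfg$threshold, c(-60, -60, -80, -60))
  expect_error(set_threshold(cfg, 2, +20), "threshold")
  expect_error(threshold_config(2, +10), "threshold")
  expect_error(threshold_config(2, -10, holdoff_ms = -1), "holdoff_ms")
})
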