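test_that("zero-phase band-pass gain matches the analytic response", {
  fs <- 30000
  spec <- filter_spec()   # 600-6000 Hz, order 4
  t <- seq(0, 1, by = 1 / fs)
  mid <- 10000:20000      # steady-state region, away from edges
  amp <- function(y) sqrt(2 * mean(y[mid]^2))  # phase-grid-proof amplitude
  # passband: 1 kHz within 1% of unity
  y <- bandpass_filter(sin(2 * pi * 1000 * t), spec, fs)
  expect_lt(abs(amp(y) - 1), 0.01)
  expect_lt(abs(amp(y) - bandpass_gain(spec, fs, 1000)), 0.01)
  # stopband: 50 Hz attenuated below 5%
  y50 <- bandpass_filter(sin(2 * pi * 50 * t), spec, fs)
  expect_lt(max(abs(y50[mid])), 0.05)
  expect_lt(abs(amp(y50) - bandpass_gain(spec, fs, 50)), 1e-6)
  # a mid-band tone agrees with the analytic curve too
  y3k <- bandpass_filter(sin(2 * pi * 3000 * t), spec, fs)
  expect_lt(abs(amp(y3k) - bandpass_gain(spec, fs, 3000)), 0.01)
})

test_that("forward-backward filtering has zero phase shift", {
  fs <- 30000
  x <- rep(0, 3000); x[1500] <- 1
  y <- bandpass_filter(x, filter_spec(), fs)
  expect_equal(which.max(abs(y)), 1500)
  # symmetric impulse response around the impulse
  expect_equal(y[1500 + 1:200], y[1500 - 1:200], tolerance = 1e-6)
  expect_equal(length(y), length(x))
})

test_that("invalid cutoffs are rejected", {
  expect_error(filter_spec(low_cut = 0), "low_cut")
  expect_error(filter_spec(600, 500), "high_cut")
  expect_error(butter_bandpass(filter_spec(600, 16000), fs = 30000),
               "high_cut")
})

test_that("largest-spike censoring keeps the biggest of near-coincident spikes", {
  fs <- 30000
  # one event seen on 4 wires at ~equal times
  d <- data.frame(channel = 1:4,
                  timestamp = c(1000, 1001, 1002, 1000),
                  peak_amplitude = c(-80, -120, -90, -70))
  m <- merge_and_censor(d, censor_ms = 0.75, sampling_rate = fs)
  expect_equal(nrow(m), 1)
  expect_equal(m$peak_amplitude, -120)
  expect_equal(m$channel, 2)

  single <- d[2, ]
  expect_equal(merge_and_censor(single, 0.75, fs)$timestamp, 1001)

  far <- data.frame(channel = c(1, 1), timestamp = c(1000, 1000 + 2 * 23),
                    peak_amplitude = c(-80, -90))
  expect_equal(nrow(merge_and_censor(far, 0.75, fs)), 2)

  # list-of-wires input is concatenated
  m2 <- merge_and_censor(split(d, d$channel), 0.75, fs)
  expect_equal(m2$peak_amplitude, -120)
})

test_that("merge_and_censor matches the brute-force greedy oracle", {
  set.seed(71)
  fs <- 30000
  censor <- ms_to_samples(0.75, fs)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    d <- data.frame(channel = sample(1:4, n, replace = TRUE),
                    timestamp = sort(sample(1:2000, n)),
                    peak_amplitude = -round(runif(n, 50, 200), 1))
    m <- merge_and_censor(d, 0.75, fs)
    o <- oracle_censor(d, censor)
    expect_equal(m$timestamp, o$timestamp)
    expect_equal(m$peak_amplitude, o$peak_amplitude)
    # invariants: no two survivors within the censor window; never grows
    if (nrow(m) > 1) expect_true(all(diff(m$timestamp) >= censor))
    expect_lte(nrow(m), nrow(d))
  }
})

test_that("tetrode merging finds more unique true spikes than any single wire", {
  # per-wire amplitude variation: each wire misses different spikes, the
  # merged tetrode view misses fewer
  set.seed(81)
  rec <- simulate_recording(simulation_config(
    duration_s = 8, n_channels = 4, noise_sd = 20,
    units = list(
      unit_spec(1:4, gains = c(1.0, 0.55, 0.75, 0.5), background_rate_hz = 8,
                template = spike_template(30000, -95)),
      unit_spec(1:4, gains = c(0.5, 1.0, 0.55, 0.75), background_rate_hz = 8,
                template = spike_template(30000, -90))),
    seed = 82))
  truth <- sort(unique(c(rec$ground_truth$units[[1]]$timestamp,
                         rec$ground_truth$units[[2]]$timestamp)))
  cfg <- threshold_config(4, -60)
  filt <- bandpass_filter(rec$signal, filter_spec(), rec$sampling_rate)
  per_ch <- detect_continuous(filt, rec$sampling_rate, cfg)
  merged <- merge_and_censor(per_ch, 0.75, rec$sampling_rate)
  hits <- function(det_ts) sum(vapply(truth, function(t)
    any(abs(det_ts - t) <= 15), logical(1)))
  merged_hits <- hits(merged$timestamp)
  wire_hits <- vapply(1:4, function(ch)
    hits(per_ch$timestamp[per_ch$channel == ch]), numeric(1))
  expect_gt(merged_hits, max(wire_hits))
})

test_that("the light-response criterion separates flat from evoked histograms", {
  flat <- list(counts = rep(3, 70), edges = seq(-20, 50), n_events = 100)
  expect_equal(light_response_criterion(flat)$outcome, "negative")

  few <- list(counts = rep(3, 70), edges = seq(-20, 50), n_events = 5)
  expect_equal(light_response_criterion(few)$outcome, "insufficient")

  # simulator-tagged unit: positive with the peak bin at the 3 ms latency
  rec <- tiny_tagged_recording(seed = 91, duration_s = 10)
  res <- run_online(as_packets(rec), threshold_config(4, -80))
  crit <- light_response_criterion(res$peth)
  expect_equal(crit$outcome, "positive")
  expect_gte(crit$peak_bin_ms, 2)
  expect_lt(crit$peak_bin_ms, 4)
  expect_gt(crit$score, 3)
})

test_that("concordance arithmetic and guards", {
  # perfect agreement
  r <- detection_records(1, 1:4, c(TRUE, TRUE, FALSE, FALSE),
                         c(TRUE, TRUE, FALSE, FALSE))
  ct <- concordance(r)
  expect_equal(ct$sensitivity, 100)
  expect_equal(ct$specificity, 100)
  # all negative: sensitivity undefined, never reported as zero
  rn <- detection_records(1, 1:3, rep(FALSE, 3), rep(FALSE, 3))
  ctn <- concordance(rn)
  expect_true(is.na(ctn$sensitivity))
  expect_equal(ctn$specificity, 100)
  expect_output(print(ctn), "undefined")
  expect_error(concordance(rn[0, ]), "no records")
  expect_error(detection_records(c(1, 1), c(2, 2), c(TRUE, TRUE),
                                 c(TRUE, FALSE)), "unique")
})

test_that("time accounting handles the degenerate equalities", {
  b <- time_budget(n_animals = 1, actual_hours = 7.5)
  r <- time_savings(b)
  expect_equal(r$baseline_hours_per_animal, 7.5)
  expect_equal(r$recording_saved_h, 0)
  expect_equal(r$sessions_avoided, 0)
  expect_equal(r$total_saved_h, 0)
  expect_warning(time_savings(time_budget(1, actual_hours = 9)),
                 "negative")
  expect_error(time_budget(2, actual_hours = 5), "actual_hours")
})
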