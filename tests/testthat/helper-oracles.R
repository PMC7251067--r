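# Independent brute-force oracles: deliberately naive re-implementations
# used only to check the real code paths, plus tiny fixture builders.

# round a vector through float32, the wire/recording precision
f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          numeric(), n = length(x), size = 4L, endian = "little")
}

# sample-by-sample threshold/holdoff state machine (negative polarity);
# returns peak indices. Independent of the rle-based implementation.
oracle_detect <- function(x, thr, holdoff_samples) {
  peaks <- integer()
  in_run <- FALSE
  run_start <- NA_integer_
  last_peak <- -Inf
  for (i in seq_along(x)) {
    if (!in_run && x[i] < thr) {
      in_run <- TRUE
      run_start <- i
    } else if (in_run && x[i] >= thr) {
      if (run_start - last_peak >= holdoff_samples) {
        seg <- x[run_start:(i - 1)]
        p <- run_start + which.min(seg) - 1L
        peaks <- c(peaks, p)
        last_peak <- p
      }
      in_run <- FALSE
    }
  }
  if (in_run && run_start - last_peak >= holdoff_samples) {
    seg <- x[run_start:length(x)]
    peaks <- c(peaks, run_start + which.min(seg) - 1L)
  }
  peaks
}

# brute-force greedy-by-amplitude censoring: repeatedly take the largest
# remaining |amplitude| and delete everything within the censor window
oracle_censor <- function(d, censor_samples) {
  kept <- d[0, ]
  remaining <- d
  while (nrow(remaining)) {
    ord <- order(-abs(remaining$peak_amplitude), remaining$timestamp,
                 remaining$channel)
    best <- remaining[ord[1], ]
    kept <- rbind(kept, best)
    remaining <- remaining[abs(remaining$timestamp - best$timestamp) >=
                             censor_samples, , drop = FALSE]
  }
  kept <- kept[order(kept$timestamp, kept$channel), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# double-loop PETH: count (spike, event) pairs per relative-time bin
oracle_peth <- function(spike_ts, event_ts, fs, pre_ms, post_ms,
                        bin_width_ms = 1) {
  edges <- seq(-pre_ms, post_ms, by = bin_width_ms)
  counts <- integer(length(edges) - 1)
  for (e in event_ts) {
    for (s in spike_ts) {
      r <- (s - e) / fs * 1000
      if (r >= -pre_ms && r < post_ms) {
        b <- floor((r + pre_ms) / bin_width_ms) + 1
        counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# small tagged-tetrode recording used by several tests
tiny_tagged_recording <- function(seed, duration_s = 5, noise_sd = 20,
                                  probability = 0.8, intensity = 0,
                                  n_channels = 4) {
  cfg <- simulation_config(
    duration_s = duration_s, n_channels = n_channels, noise_sd = noise_sd,
    units = list(unit_spec(seq_len(n_channels),
                           gains = seq(1, 0.6, length.out = n_channels),
                           background_rate_hz = 5,
                           evoked = list(probability = probability,
                                         latency_ms = 3, jitter_ms = 0.5))),
    artifact = if (intensity > 0)
      artifact_spec(channels = seq_len(n_channels), intensity = intensity),
    stimulus = stimulus_spec(), seed = seed)
  simulate_recording(cfg)
}
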