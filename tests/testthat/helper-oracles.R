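# Independent brute-force oracles. These deliberately use plain loops and
# explicit comparisons, sharing no code path with the package functions
# they check.

# Exhaustive threshold scan + greedy dead-time filter: returns accepted
# peak sample indices.
oracle_detect_idx <- function(x, sigma, fs, k = 5, dead_time_s = 0.003) {
  n <- length(x)
  thr <- -k * sigma
  cand <- logical(n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (x[i] < x[i - 1L] && x[i] <= x[i + 1L] && x[i] < thr) cand[i] <- TRUE
    }
  }
  acc <- integer(0)
  last <- -Inf
  for (i in which(cand)) {
    if (i - last > dead_time_s * fs) {
      acc <- c(acc, i)
      last <- i
    }
  }
  acc
}

# Exhaustive pairwise latency enumeration into half-open bins
# [k*bin, (k+1)*bin), latency 0 excluded, latency == window in the last bin.
oracle_stth_counts <- function(ref, tgt, window_s = 0.016, bin_s = 5e-5) {
  nbins <- as.integer(round(window_s / bin_s))
  edges <- (0:nbins) * bin_s
  counts <- integer(nbins)
  for (r in ref) {
    for (t in tgt) {
      lat <- t - r
      if (lat <= 0 || lat > window_s) next
      for (kk in seq_len(nbins)) {
        hit <- lat >= edges[kk] &&
          (lat < edges[kk + 1L] || (kk == nbins && lat <= edges[kk + 1L]))
        if (hit) {
          counts[kk] <- counts[kk] + 1L
          break
        }
      }
    }
  }
  counts
}

# Greedy dead-time filter applied to already-detected spike times.
oracle_dead_time <- function(times_s, dead_time_s = 0.003) {
  acc <- numeric(0)
  last <- -Inf
  for (t in times_s) {
    if (t - last > dead_time_s) {
      acc <- c(acc, t)
      last <- t
    }
  }
  acc
}

# Random trace generator for detection-oracle checks: Gaussian noise with
# occasional inserted large negative deflections.
make_random_trace <- function(seed, max_len = 10000L, fs = 25000) {
  set.seed(seed)
  n <- sample(50:max_len, 1L)
  x <- rnorm(n)
  n_spk <- rpois(1L, 3)
  if (n_spk > 0L && n > 20L) {
    at <- sample(5:(n - 5L), min(n_spk, n - 10L))
    x[at] <- x[at] - runif(length(at), 5, 12)
  }
  x
}

# One seeded recovery run: simulate a 5-electrode channel, detect, estimate
# the channel's median conduction speed.
recovery_run <- function(speed_m_s, seed, duration_s = 40,
                         snr = 8, noise_free = FALSE) {
  g <- default_geometry()
  sigma <- ptp_to_sigma(2e-4, 25000L)
  cfg <- sim_config(duration_s = duration_s,
                    conduction_speed_m_s = speed_m_s,
                    spike_amplitude_v = snr * sigma,
                    noise_sigma_v = if (noise_free) 0 else sigma,
                    seed = seed)
  # late source spikes can propagate past the recording end; dropping them
  # is expected here
  rec <- suppressWarnings(simulate_recording(g, cfg))
  # a silent noise-free trace has no MAD noise floor; fix the detection
  # sigma so the 5-sigma threshold sits at half the spike amplitude
  trains <- if (noise_free)
    detect_recording(rec, sigma_override = cfg$spike_amplitude_v / 10)
  else detect_recording(rec)
  speeds <- estimate_conduction_speed(g, trains)
  list(speeds = speeds,
       summary = suppressMessages(channel_speed_summary(speeds)),
       trains = trains, geometry = g, config = cfg)
}
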