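# Preprocessing and spike detection: zero-phase Butterworth high-pass at
# 200 Hz, robust noise sigma from the median absolute deviation
# (sigma = 1.4826 * MAD), negative-peak detection at 5 sigma, and a 3 ms
# dead time that discards duplicate threshold crossings of the same spike.

#' Zero-phase Butterworth high-pass filter
#'
#' Order-4 Butterworth applied forward and backward (filtfilt), so the
#' filter contributes no net phase shift and detected peak times are not
#' skewed by filter delay. Offline analysis permits the acausal pass.
#'
#' @param trace numeric voltage trace.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param cutoff_hz high-pass cutoff, Hz (default 200); must be below the
#'   Nyquist frequency.
#' @param order filter order (default 4).
#' @return filtered trace, same length as the input.
#' @export
highpass_filter <- function(trace, sampling_rate_hz, cutoff_hz = 200,
                            order = 4L) {
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  check_positive(cutoff_hz, "cutoff_hz")
  check_positive(order, "order")
  if (cutoff_hz >= sampling_rate_hz / 2)
    stop_param("cutoff_hz", "must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (sampling_rate_hz / 2),
                       type = "high")
  filtfilt_ba(bf$b, bf$a, as.numeric(trace))
}

# Single-pass IIR application of a (b, a) filter with steady-state initial
# conditions for a constant input of x[1]: a DC trace comes out at its
# steady-state gain (0 for a high-pass) with no startup transient. Run
# through stats::filter's compiled convolution/recursive routines for
# speed on multi-million-sample traces.
#' @keywords internal
apply_ba <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(x[1], nb - 1L), x), b, method = "convolution",
                     sides = 1L)
  v <- v[-seq_len(nb - 1L)]
  y0 <- x[1] * sum(b) / sum(a)  # DC steady state
  as.numeric(stats::filter(v, -a[-1], method = "recursive",
                           init = rep(y0, length(a) - 1L)))
}

# Zero-phase forward-backward pass with odd-extension padding at both ends
# (the filtfilt convention), so edge transients stay off the trace.
#' @keywords internal
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 150L)
  if (pad < 1L) {
    y <- apply_ba(b, a, x)
    return(rev(apply_ba(b, a, rev(y))))
  }
  pre <- 2 * x[1] - x[(pad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- apply_ba(b, a, c(pre, x, post))
  y <- rev(apply_ba(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Robust noise estimate from the median absolute deviation
#'
#' sigma = b * MAD with b = 1.4826 and MAD = median(|x - median(x)|).
#' The MAD is far less sensitive to the spikes riding on the trace than
#' the sample standard deviation, so the threshold tracks the noise floor
#' rather than the spike amplitudes. b is the reciprocal of the 0.75
#' normal quantile, making sigma unbiased for Gaussian noise.
#'
#' @param filtered_trace non-empty numeric trace (after high-pass filtering).
#' @param electrode_id optional electrode identifier carried into the result.
#' @return list of class `noise_estimate`: `electrode_id`, `sigma_v`,
#'   `mad_v`, `b` (1.4826).
#' @export
estimate_noise_sigma <- function(filtered_trace, electrode_id = NA_character_) {
  if (length(filtered_trace) == 0L)
    stop("invalid input: empty trace", call. = FALSE)
  b <- 1.4826
  mad_v <- stats::median(abs(filtered_trace - stats::median(filtered_trace)))
  structure(list(electrode_id = electrode_id, sigma_v = b * mad_v,
                 mad_v = mad_v, b = b),
            class = "noise_estimate")
}

#' Detect negative-peak spikes with a dead time
#'
#' Candidate events are local minima whose value falls below `-k * sigma`.
#' Candidates are scanned in time order; any candidate within `dead_time_s`
#' after the last accepted event is discarded as a duplicate (greedy rule:
#' each accepted spike opens a fresh dead-time window). On equal-valued
#' adjacent minima the earliest sample wins.
#'
#' @param filtered_trace high-pass-filtered trace, volts.
#' @param sigma noise standard deviation (from [estimate_noise_sigma()]), volts.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param k threshold multiplier (default 5).
#' @param dead_time_s dead time, seconds (default 0.003).
#' @param electrode_id optional identifier carried into the result.
#' @return list of class `spike_train`: `electrode_id`, `times_s` (sorted,
#'   consecutive times > dead time apart), `amplitudes_v` (signed peak
#'   values), `threshold_v` (= -k * sigma), `sigma_v`.
#' @export
detect_spikes <- function(filtered_trace, sigma, sampling_rate_hz, k = 5,
                          dead_time_s = 0.003,
                          electrode_id = NA_character_) {
  check_nonneg(sigma, "sigma")
  check_positive(k, "k")
  check_nonneg(dead_time_s, "dead_time_s")
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  x <- as.numeric(filtered_trace)
  if (sigma == 0 && any(x != 0))
    stop("degenerate threshold: sigma is 0 on a non-zero trace", call. = FALSE)
  thr <- -k * sigma
  n <- length(x)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    # strict drop from the left, non-strict to the right: earliest sample
    # of a flat minimum wins
    is_min <- x[i] < x[i - 1L] & x[i] <= x[i + 1L] & x[i] < thr
    cand <- i[is_min]
  } else cand <- integer(0)
  keep <- logical(length(cand))
  dead_samples <- dead_time_s * sampling_rate_hz
  last <- -Inf
  for (j in seq_along(cand)) {
    if (cand[j] - last > dead_samples) {
      keep[j] <- TRUE
      last <- cand[j]
    }
  }
  acc <- cand[keep]
  structure(list(electrode_id = electrode_id,
                 times_s = (acc - 1L) / sampling_rate_hz,
                 amplitudes_v = x[acc],
                 threshold_v = thr, sigma_v = sigma),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train '%s': %d spikes, threshold %.3g V\n",
              x$electrode_id, length(x$times_s), x$threshold_v))
  invisible(x)
}

#' Filter and detect spikes on every electrode of a recording
#'
#' Runs the high-pass filter, per-electrode MAD noise estimate and
#' negative-peak detection over a full recording.
#'
#' @param recording a `recording` (see [render_recording()]) or any list with
#'   `traces_v`, `sampling_rate_hz`, `electrode_ids`.
#' @param cutoff_hz,order high-pass settings (defaults 200 Hz, order 4).
#' @param k,dead_time_s detection settings (defaults 5, 3 ms).
#' @param sigma_override optional fixed noise sigma (volts) applied to every
#'   electrode instead of the per-electrode MAD estimate; useful for
#'   noiseless validation data, where the MAD of a silent trace degenerates.
#' @return named list of `spike_train`, one per electrode.
#' @export
detect_recording <- function(recording, cutoff_hz = 200, order = 4L, k = 5,
                             dead_time_s = 0.003, sigma_override = NULL) {
  fs <- recording$sampling_rate_hz
  out <- lapply(seq_along(recording$electrode_ids), function(e) {
    f <- highpass_filter(recording$traces_v[e, ], fs, cutoff_hz, order)
    sig <- if (is.null(sigma_override))
      estimate_noise_sigma(f, recording$electrode_ids[e])$sigma_v
    else sigma_override
    detect_spikes(f, sig, fs, k, dead_time_s,
                  electrode_id = recording$electrode_ids[e])
  })
  names(out) <- recording$electrode_ids
  out
}

#' Spike trains as a tidy table
#'
#' @param spike_trains named list of `spike_train`.
#' @return data.frame with columns `electrode_id, time_s, amplitude_v,
#'   sigma_v`, one row per accepted spike.
#' @export
spikes_table <- function(spike_trains) {
  if (inherits(spike_trains, "spike_train")) spike_trains <- list(spike_trains)
  rows <- lapply(spike_trains, function(st) {
    if (length(st$times_s) == 0L) return(NULL)
    data.frame(electrode_id = st$electrode_id, time_s = st$times_s,
               amplitude_v = st$amplitudes_v, sigma_v = st$sigma_v,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(electrode_id = character(0), time_s = numeric(0),
                      amplitude_v = numeric(0), sigma_v = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
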