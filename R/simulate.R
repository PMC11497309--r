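# Synthetic ground-truth recordings: homogeneous Poisson spike trains of an
# axon bundle entering a microchannel, action potentials propagating down
# the channel at a fixed conduction speed (delay = distance / speed across
# the electrodes), biphasic negative-dominant waveforms, and white Gaussian
# electrode noise at 25 kHz. Every recording carries its ground truth so
# detection and conduction-speed estimation can be scored against it.

#' Simulation configuration
#'
#' Defaults emulate the recording conditions of microchannel MEA cultures:
#' 25 kHz sampling, spike amplitude 0.4 mV against noise whose 1 s
#' peak-to-peak level is about 0.2 mV (i.e. Gaussian sigma ~ 24 uV).
#'
#' @param sampling_rate_hz samples per second (default 25000).
#' @param duration_s recording length in seconds.
#' @param firing_rate_hz Poisson rate of the source unit, Hz.
#' @param conduction_speed_m_s propagation speed along the channel, m/s.
#' @param spike_amplitude_v peak negative spike amplitude, volts (default 4e-4).
#' @param noise_sigma_v Gaussian noise standard deviation, volts. The default
#'   converts a 0.2 mV peak-to-peak level over 1 s windows via
#'   [ptp_to_sigma()].
#' @param seed integer master seed; fixed seed gives bit-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate_hz = 25000, duration_s = 60,
                       firing_rate_hz = 5, conduction_speed_m_s = 0.5,
                       spike_amplitude_v = 4e-4,
                       noise_sigma_v = ptp_to_sigma(2e-4, round(sampling_rate_hz)),
                       seed = 1L) {
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  check_positive(duration_s, "duration_s")
  check_positive(firing_rate_hz, "firing_rate_hz")
  check_positive(conduction_speed_m_s, "conduction_speed_m_s")
  check_positive(spike_amplitude_v, "spike_amplitude_v")
  check_nonneg(noise_sigma_v, "noise_sigma_v")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 firing_rate_hz = firing_rate_hz,
                 conduction_speed_m_s = conduction_speed_m_s,
                 spike_amplitude_v = spike_amplitude_v,
                 noise_sigma_v = noise_sigma_v, seed = as.integer(seed)),
            class = "sim_config")
}

#' Convert a peak-to-peak noise level to a Gaussian sigma
#'
#' Recording noise is usually quoted peak-to-peak over an inspection window;
#' a zero-mean Gaussian trace of n samples has expected range
#' 2 E\[max of n standard normals\], evaluated here by numerical
#' integration of the exact order-statistic density.
#'
#' @param ptp_v peak-to-peak level, volts.
#' @param n_samples samples in the inspection window (default 25000, i.e.
#'   1 s at 25 kHz).
#' @return the Gaussian standard deviation in volts.
#' @examples
#' ptp_to_sigma(2e-4) # ~2.4e-5 V for 0.2 mV p-p
#' @export
ptp_to_sigma <- function(ptp_v, n_samples = 25000L) {
  check_positive(ptp_v, "ptp_v")
  n <- check_positive(n_samples, "n_samples")
  emax <- stats::integrate(function(x) x * n * stats::dnorm(x) * stats::pnorm(x)^(n - 1),
                           lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  ptp_v / (2 * emax)
}

#' Generate a homogeneous Poisson spike train
#'
#' @param rate_hz firing rate, Hz (>= 0).
#' @param duration_s duration, seconds (>= 0).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return sorted, unique spike times in `[0, duration_s)`, seconds.
#' @export
generate_poisson_train <- function(rate_hz, duration_s, seed = NULL) {
  check_nonneg(rate_hz, "rate_hz")
  check_nonneg(duration_s, "duration_s")
  with_seed(seed, {
    n <- stats::rpois(1L, rate_hz * duration_s)
    sort(unique(stats::runif(n, 0, duration_s)))
  })
}

#' Propagate source spike times down a channel
#'
#' Arrival time at each electrode is the source time plus
#' position / speed; the inverse of the latency-peak speed estimate.
#'
#' @param source_times sorted spike times at the channel entrance, seconds.
#' @param geometry a [channel_geometry()].
#' @param speed_m_s conduction speed, m/s (> 0).
#' @return named list of per-electrode arrival-time vectors (seconds).
#' @examples
#' g <- default_geometry()
#' propagate(0.1, g, 0.5)  # 500 um at 0.5 m/s -> 1 ms delay per electrode
#' @export
propagate <- function(source_times, geometry, speed_m_s) {
  check_positive(speed_m_s, "speed_m_s")
  stopifnot(inherits(geometry, "channel_geometry"))
  delays <- geometry$positions_um * 1e-6 / speed_m_s
  out <- lapply(delays, function(d) source_times + d)
  names(out) <- geometry$electrode_ids
  out
}

#' Ground truth for a simulated unit
#'
#' @param unit_id unit identifier.
#' @param source_times_s sorted source spike times, seconds.
#' @param geometry a [channel_geometry()].
#' @param conduction_speed_m_s conduction speed, m/s.
#' @return list of class `ground_truth` with per-electrode arrival times.
#' @export
ground_truth <- function(unit_id, source_times_s, geometry,
                         conduction_speed_m_s) {
  structure(list(unit_id = as.character(unit_id),
                 source_times_s = source_times_s,
                 conduction_speed_m_s = conduction_speed_m_s,
                 arrival_times_s = propagate(source_times_s, geometry,
                                             conduction_speed_m_s)),
            class = "ground_truth")
}

#' Biphasic extracellular spike template
#'
#' A fixed template of total width ~1 ms: a dominant negative lobe followed
#' by a smaller positive lobe, scaled so its global minimum is exactly
#' `-amplitude_v` at the centre sample. Real spike shapes vary along an
#' axon; that variability is deliberately not modelled.
#'
#' @param sampling_rate_hz sampling rate, Hz.
#' @param amplitude_v peak negative amplitude, volts.
#' @return numeric vector of odd length ~ 1 ms with attribute `center`
#'   (index of the minimum).
#' @export
spike_template <- function(sampling_rate_hz, amplitude_v) {
  check_positive(sampling_rate_hz, "sampling_rate_hz")
  check_positive(amplitude_v, "amplitude_v")
  half <- floor(0.0005 * sampling_rate_hz)  # +-0.5 ms
  t_ms <- (seq(-half, half)) / sampling_rate_hz * 1000
  shape <- -exp(-t_ms^2 / (2 * 0.1^2)) + 0.35 * exp(-(t_ms - 0.35)^2 / (2 * 0.18^2))
  w <- amplitude_v * shape / abs(min(shape))
  structure(w, center = half + 1L)
}

#' Render a voltage-trace recording from ground truth
#'
#' Each arrival event inserts the biphasic template centred at the arrival
#' time rounded to the nearest sample (quantization error at most half a
#' sample, 0.02 ms at 25 kHz); independent white Gaussian noise of
#' `noise_sigma_v` is then added per electrode. Arrivals beyond the
#' recording duration are dropped with a warning. Waveforms overhanging the
#' trace ends are clipped.
#'
#' @param truths a `ground_truth` or list of them (superposed multi-unit mode).
#' @param geometry a [channel_geometry()].
#' @param config a [sim_config()].
#' @return list of class `recording`: `traces_v` (electrode x sample matrix,
#'   volts), `sampling_rate_hz`, `electrode_ids`, `duration_s`,
#'   `ground_truth` (the input), `config`.
#' @export
render_recording <- function(truths, geometry, config) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(config, "sim_config"))
  if (inherits(truths, "ground_truth")) truths <- list(truths)
  fs <- config$sampling_rate_hz
  n_samp <- round(config$duration_s * fs)
  n_el <- length(geometry$electrode_ids)
  w <- spike_template(fs, config$spike_amplitude_v)
  ctr <- attr(w, "center")
  L <- length(w)
  traces <- matrix(0, nrow = n_el, ncol = n_samp,
                   dimnames = list(geometry$electrode_ids, NULL))
  n_dropped <- 0L
  for (tr in truths) {
    for (e in seq_len(n_el)) {
      eid <- geometry$electrode_ids[e]
      arr <- tr$arrival_times_s[[eid]]
      beyond <- arr >= config$duration_s
      n_dropped <- n_dropped + sum(beyond)
      centers <- round(arr[!beyond] * fs) + 1L  # nearest-sample quantization
      for (c0 in centers) {
        i0 <- max(1L, c0 - ctr + 1L)
        i1 <- min(n_samp, c0 + (L - ctr))
        if (i0 > i1) next
        traces[e, i0:i1] <- traces[e, i0:i1] + w[(i0 - c0 + ctr):(i1 - c0 + ctr)]
      }
    }
  }
  if (n_dropped > 0L)
    warning(sprintf("%d arrival(s) beyond duration dropped", n_dropped))
  if (config$noise_sigma_v > 0) {
    for (e in seq_len(n_el)) {
      noise <- with_seed(derive_seed(config$seed, 1000L + e),
                         stats::rnorm(n_samp, 0, config$noise_sigma_v))
      traces[e, ] <- traces[e, ] + noise
    }
  }
  structure(list(traces_v = traces, sampling_rate_hz = fs,
                 electrode_ids = geometry$electrode_ids,
                 duration_s = config$duration_s,
                 ground_truth = truths, config = config),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d electrodes x %d samples (%.1f s at %g kHz)\n",
              nrow(x$traces_v), ncol(x$traces_v), x$duration_s,
              x$sampling_rate_hz / 1000))
  invisible(x)
}

#' Simulate a complete microchannel recording
#'
#' Convenience wrapper: draws Poisson source trains (one per unit),
#' propagates them down the channel and renders the traces.
#'
#' @param geometry a [channel_geometry()].
#' @param config a [sim_config()].
#' @param n_units number of superposed source units (default 1). In
#'   multi-unit mode unit k propagates at
#'   `conduction_speed_m_s * speed_factors[k]`.
#' @param speed_factors multipliers per unit (recycled; default 1).
#' @return a `recording` with ground truth attached.
#' @export
simulate_recording <- function(geometry, config, n_units = 1L,
                               speed_factors = 1) {
  stopifnot(n_units >= 1L)
  speed_factors <- rep_len(speed_factors, n_units)
  truths <- lapply(seq_len(n_units), function(k) {
    src <- generate_poisson_train(config$firing_rate_hz, config$duration_s,
                                  seed = derive_seed(config$seed, k))
    ground_truth(sprintf("unit%d", k), src, geometry,
                 config$conduction_speed_m_s * speed_factors[k])
  })
  render_recording(truths, geometry, config)
}
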