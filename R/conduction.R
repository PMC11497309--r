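# Conduction-speed estimation from spike-triggered time histograms (STTH).
# For an ordered electrode pair the STTH accumulates, for every spike on the
# upstream (reference) electrode, the latencies of downstream (target)
# spikes within a 16 ms window into 0.05 ms bins. A latency peak above the
# baseline indicates propagation, and the conduction speed is the electrode
# separation divided by the lower edge of the peak bin:
#     v [m/s] = d_elec [mm] / t_peak [ms].
# The 16 ms window puts the resolvable speed floor at d_elec / 16 ms per
# pair (~0.15 m/s for a 2.4 mm separation).

#' Build a spike-triggered time histogram between two electrodes
#'
#' For every reference spike r, every target spike t with latency
#' `t - r` in `(0, window_s]` increments the bin with half-open edges
#' `[k*bin_s, (k+1)*bin_s)`; a latency of exactly 0 is excluded (a
#' coincident spike is not propagation) and a latency exactly equal to the
#' window falls in the last bin. All target spikes in the window are
#' counted, not just the first.
#'
#' @param ref_train sorted reference (upstream) spike times, seconds.
#' @param target_train sorted target (downstream) spike times, seconds.
#' @param window_s window length, seconds (default 0.016); must be an
#'   integer multiple of `bin_s`.
#' @param bin_s bin width, seconds (default 5e-5).
#' @return list of class `stth`: `counts` (integer, length window/bin),
#'   `bin_lower_ms` (lower edges, ms), `n_ref_spikes`, `window_s`, `bin_s`.
#' @export
build_stth <- function(ref_train, target_train, window_s = 0.016,
                       bin_s = 5e-5) {
  check_positive(window_s, "window_s")
  check_positive(bin_s, "bin_s")
  nbins <- window_s / bin_s
  if (abs(nbins - round(nbins)) > 1e-9 * nbins)
    stop_param("window_s", "must be an integer multiple of bin_s")
  nbins <- as.integer(round(nbins))
  edges <- (0:nbins) * bin_s
  counts <- integer(nbins)
  ref <- as.numeric(ref_train)
  tgt <- as.numeric(target_train)
  if (is.unsorted(ref)) stop_param("ref_train", "must be sorted")
  if (is.unsorted(tgt)) stop_param("target_train", "must be sorted")
  if (length(ref) > 0L && length(tgt) > 0L) {
    # for each ref spike, the run of target spikes with latency in (0, window]
    lo <- findInterval(ref, tgt, left.open = TRUE) + 1L  # first target > ref
    hi <- findInterval(ref + window_s, tgt)              # last target <= ref + window
    for (j in seq_along(ref)) {
      if (lo[j] > hi[j]) next
      lat <- tgt[lo[j]:hi[j]] - ref[j]
      lat <- lat[lat > 0]
      if (length(lat) == 0L) next
      k <- findInterval(lat, edges, rightmost.closed = TRUE)
      tb <- tabulate(k, nbins)
      counts <- counts + tb
    }
  }
  structure(list(counts = counts, bin_lower_ms = edges[seq_len(nbins)] * 1000,
                 n_ref_spikes = length(ref), window_s = window_s,
                 bin_s = bin_s),
            class = "stth")
}

#' @export
print.stth <- function(x, ...) {
  cat(sprintf("stth: %d bins of %.2f ms, %d ref spikes, %d latencies\n",
              length(x$counts), x$bin_s * 1000, x$n_ref_spikes,
              sum(x$counts)))
  invisible(x)
}

#' Locate the latency peak of an STTH and test it against baseline
#'
#' The peak bin is the argmax of the counts (earliest bin on ties — the
#' more conservative, higher speed bound). The peak is deemed significant
#' when (i) the reference train has at least `min_ref_spikes` spikes,
#' (ii) the peak count exceeds mean(counts) + z * sd(counts) over all bins,
#' and (iii) the peak count exceeds a Bonferroni-corrected Poisson upper
#' quantile at the mean bin count. The third condition guards the sparse
#' regime: with a few counts scattered over 320 bins, the maximum of 320
#' roughly Poisson bins routinely exceeds mean + 3 sd, so the sd criterion
#' alone would flag chance peaks (e.g. on a reversed, non-propagating
#' pair); a genuine propagation peak collects a large share of the
#' reference spikes and clears both. A peak whose lower edge is 0 ms
#' cannot yield a speed (division by zero) and is reported non-significant.
#'
#' @param histogram an `stth` from [build_stth()].
#' @param min_ref_spikes minimum reference spikes for significance (default 50).
#' @param z baseline exceedance in bin-count standard deviations (default 3).
#' @param guard_alpha family-wise false-peak rate of the Poisson guard
#'   (default 0.001 across all bins).
#' @return list: `t_peak_ms` (lower edge of the peak bin; NA if the
#'   histogram is empty), `peak_count`, `significant`.
#' @export
find_latency_peak <- function(histogram, min_ref_spikes = 50, z = 3,
                              guard_alpha = 0.001) {
  stopifnot(inherits(histogram, "stth"))
  cts <- histogram$counts
  if (all(cts == 0L))
    return(list(t_peak_ms = NA_real_, peak_count = 0L, significant = FALSE))
  i <- which.max(cts)  # earliest bin on ties
  peak <- cts[i]
  t_peak <- histogram$bin_lower_ms[i]
  baseline <- mean(cts) + z * stats::sd(cts)
  guard <- stats::qpois(1 - guard_alpha / length(cts), mean(cts))
  sig <- histogram$n_ref_spikes >= min_ref_spikes &&
    peak > baseline && peak > guard && t_peak > 0
  list(t_peak_ms = t_peak, peak_count = as.integer(peak), significant = sig)
}

#' Estimate conduction speeds along a microchannel
#'
#' For every ordered upstream-to-downstream electrode pair of the channel,
#' builds the STTH, locates the latency peak and converts it to a speed:
#' speed = d_elec / t_peak (mm/ms = m/s). Units convert from micrometres
#' and seconds to mm and ms only at this boundary.
#'
#' @param geometry a [channel_geometry()].
#' @param spike_trains named list of `spike_train` (or of bare numeric time
#'   vectors), covering the channel's electrodes.
#' @param window_s,bin_s STTH settings (defaults 16 ms, 0.05 ms).
#' @param min_ref_spikes,z significance settings for [find_latency_peak()].
#' @return data.frame with one row per ordered pair: `channel_id,
#'   ref_electrode, target_electrode, d_elec_mm, t_peak_ms, speed_m_s,
#'   peak_count, n_ref_spikes, significant, speed_floor_m_s` (the lowest
#'   speed resolvable for the pair, d_elec / window).
#' @export
estimate_conduction_speed <- function(geometry, spike_trains,
                                      window_s = 0.016, bin_s = 5e-5,
                                      min_ref_spikes = 50, z = 3) {
  stopifnot(inherits(geometry, "channel_geometry"))
  ids <- geometry$electrode_ids
  times_of <- function(id) {
    st <- spike_trains[[id]]
    if (is.null(st)) return(numeric(0))
    if (inherits(st, "spike_train")) st$times_s else as.numeric(st)
  }
  rows <- list()
  n <- length(ids)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    d_mm <- (geometry$positions_um[b] - geometry$positions_um[a]) / 1000
    h <- build_stth(times_of(ids[a]), times_of(ids[b]), window_s, bin_s)
    pk <- find_latency_peak(h, min_ref_spikes, z)
    speed <- if (!is.na(pk$t_peak_ms) && pk$t_peak_ms > 0)
      d_mm / pk$t_peak_ms else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      channel_id = geometry$channel_id,
      ref_electrode = ids[a], target_electrode = ids[b],
      d_elec_mm = d_mm, t_peak_ms = pk$t_peak_ms, speed_m_s = speed,
      peak_count = pk$peak_count, n_ref_spikes = h$n_ref_spikes,
      significant = pk$significant,
      speed_floor_m_s = d_mm / (window_s * 1000),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-channel summary speed
#'
#' The channel's conduction speed is the median over its significant pairs.
#' With no significant pair the summary is empty (a message, not an error).
#'
#' @param speed_table output of [estimate_conduction_speed()] (possibly
#'   covering several channels).
#' @return data.frame `channel_id, n_pairs, n_significant, speed_m_s`
#'   (median over significant pairs; channels without one are omitted).
#' @export
channel_speed_summary <- function(speed_table) {
  out <- lapply(split(speed_table, speed_table$channel_id), function(g) {
    sig <- g[g$significant & !is.na(g$speed_m_s), ]
    if (nrow(sig) == 0L) {
      message(sprintf("channel '%s': no significant electrode pair",
                      g$channel_id[1]))
      return(NULL)
    }
    data.frame(channel_id = g$channel_id[1], n_pairs = nrow(g),
               n_significant = nrow(sig),
               speed_m_s = stats::median(sig$speed_m_s),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    return(data.frame(channel_id = character(0), n_pairs = integer(0),
                      n_significant = integer(0), speed_m_s = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
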