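# Recording container I/O. Traces are stored as a flat little-endian
# float64 binary (electrode-major, one row per electrode) next to a JSON
# metadata sidecar carrying the sampling rate, electrode ids, dimensions
# and, when present, the simulation ground truth. The round trip is
# bit-exact. Vendor formats (e.g. MultiChannel Systems raw files) are out
# of scope; convert_vendor_recording() documents the expected layout.

#' Write a recording to disk
#'
#' Writes `<path>.f64` (raw float64 traces, electrode-major) and
#' `<path>.json` (metadata sidecar).
#'
#' @param recording a `recording` (see [render_recording()]).
#' @param path base path without extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  con <- file(paste0(path, ".f64"), "wb")
  on.exit(close(con))
  # row-major (electrode-major) so one electrode is a contiguous block
  writeBin(as.vector(t(recording$traces_v)), con, size = 8L,
           endian = "little")
  meta <- list(sampling_rate_hz = recording$sampling_rate_hz,
               electrode_ids = recording$electrode_ids,
               n_electrodes = nrow(recording$traces_v),
               n_samples = ncol(recording$traces_v),
               duration_s = recording$duration_s)
  if (!is.null(recording$ground_truth)) {
    # spike times as C99 hex-float strings: decimal JSON numbers lose the
    # last bit, hex round-trips every double exactly
    meta$ground_truth <- lapply(recording$ground_truth, function(tr) {
      list(unit_id = tr$unit_id,
           source_times_s = sprintf("%a", tr$source_times_s),
           conduction_speed_m_s = tr$conduction_speed_m_s,
           arrival_times_s = lapply(tr$arrival_times_s,
                                    function(v) sprintf("%a", v)))
    })
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path base path without extension.
#' @return a `recording` (ground truth restored when present; stored
#'   without class attributes).
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  n_el <- meta$n_electrodes
  n_samp <- meta$n_samples
  con <- file(paste0(path, ".f64"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_el * n_samp, size = 8L,
               endian = "little")
  traces <- matrix(v, nrow = n_el, byrow = TRUE,
                   dimnames = list(meta$electrode_ids, NULL))
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- lapply(meta$ground_truth, function(tr) {
      structure(list(unit_id = tr$unit_id,
                     source_times_s = as.numeric(tr$source_times_s),
                     conduction_speed_m_s = as.numeric(tr$conduction_speed_m_s),
                     arrival_times_s = lapply(tr$arrival_times_s, as.numeric)),
                class = "ground_truth")
    })
  }
  structure(list(traces_v = traces,
                 sampling_rate_hz = as.numeric(meta$sampling_rate_hz),
                 electrode_ids = meta$electrode_ids,
                 duration_s = as.numeric(meta$duration_s), ground_truth = gt,
                 config = NULL),
            class = "recording")
}

#' Vendor-format converter stub
#'
#' Reading proprietary MEA vendor files is out of scope. A converter is
#' expected to produce the container layout of [write_recording()]:
#' a float64 binary of electrode-major traces in volts plus a JSON sidecar
#' with `sampling_rate_hz`, `electrode_ids`, `n_electrodes`, `n_samples`
#' and `duration_s`.
#'
#' @param path vendor file path.
#' @export
convert_vendor_recording <- function(path) {
  stop("vendor formats are not supported; convert to the float64 + JSON ",
       "container documented in ?write_recording", call. = FALSE)
}
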