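# Channel geometry: mapping of MEA electrodes to microchannels with
# positions along the channel axis. The MEAs in the motivating experiments
# have a 500 um electrode pitch and at most five electrodes under one
# PDMS microchannel; pairwise position differences are the d_elec entering
# the conduction-speed formula.

#' Construct a microchannel electrode geometry
#'
#' @param channel_id channel identifier (scalar, one geometry per channel).
#' @param electrode_ids character or integer vector of electrode identifiers,
#'   ordered along the channel axis (upstream first).
#' @param positions_um numeric vector of positions along the channel axis in
#'   micrometres, strictly increasing, same length as `electrode_ids`.
#' @return an object of class `channel_geometry`.
#' @examples
#' channel_geometry("ch1", paste0("e", 1:5), seq(0, 2000, by = 500))
#' @export
channel_geometry <- function(channel_id, electrode_ids, positions_um) {
  if (length(channel_id) != 1L) stop_param("channel_id", "must be a scalar")
  if (length(electrode_ids) != length(positions_um))
    stop_param("positions_um", "length must match electrode_ids")
  if (length(electrode_ids) < 1L)
    stop_param("electrode_ids", "at least one electrode required")
  if (anyDuplicated(electrode_ids))
    stop_param("electrode_ids", "duplicated electrode id (at most one channel per electrode)")
  if (!is.numeric(positions_um) || anyNA(positions_um))
    stop_param("positions_um", "must be numeric, no NA")
  if (length(positions_um) > 1L && any(diff(positions_um) <= 0))
    stop_param("positions_um", "must be strictly increasing along the channel")
  structure(
    list(channel_id = as.character(channel_id),
         electrode_ids = as.character(electrode_ids),
         positions_um = as.double(positions_um)),
    class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel_geometry '%s': %d electrodes, span %.0f um\n",
              x$channel_id, length(x$electrode_ids),
              diff(range(x$positions_um))))
  invisible(x)
}

#' Default five-electrode geometry at 500 micrometre pitch
#'
#' The layout of a microchannel crossing five MEA electrodes at the standard
#' 500 um pitch (the maximum per channel on a 6 x 10 array).
#'
#' @param channel_id channel identifier.
#' @param n_electrodes number of electrodes (default 5).
#' @param pitch_um electrode spacing in micrometres (default 500).
#' @return a `channel_geometry`.
#' @export
default_geometry <- function(channel_id = "ch1", n_electrodes = 5L,
                             pitch_um = 500) {
  check_positive(pitch_um, "pitch_um")
  if (n_electrodes < 1L) stop_param("n_electrodes", "must be >= 1")
  channel_geometry(channel_id,
                   sprintf("%s_e%d", channel_id, seq_len(n_electrodes)),
                   pitch_um * (seq_len(n_electrodes) - 1))
}

#' Read / write geometry tables
#'
#' Geometry CSVs have columns `channel_id, electrode_id, position_um`,
#' one row per electrode. `read_geometry()` returns a named list of
#' `channel_geometry` objects (one per channel).
#'
#' @param path CSV file path.
#' @return for `read_geometry`, a named list of `channel_geometry`; for
#'   `write_geometry`, the path, invisibly.
#' @export
read_geometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "electrode_id", "position_um")
  if (!all(need %in% names(df)))
    stop_param("geometry", paste("CSV must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(df$electrode_id))
    stop_param("geometry", "an electrode appears in more than one row")
  out <- lapply(split(df, df$channel_id), function(g) {
    g <- g[order(g$position_um), ]
    channel_geometry(g$channel_id[1], g$electrode_id, g$position_um)
  })
  out[order(names(out))]
}

#' @param geometries a `channel_geometry` or list of them.
#' @rdname read_geometry
#' @export
write_geometry <- function(geometries, path) {
  if (inherits(geometries, "channel_geometry")) geometries <- list(geometries)
  df <- do.call(rbind, lapply(geometries, function(g) {
    data.frame(channel_id = g$channel_id, electrode_id = g$electrode_ids,
               position_um = g$positions_um, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
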