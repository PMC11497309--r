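# End-to-end pipeline: simulate (or load) -> detect -> conduction ->
# activity metrics, with a single validated config, one master seed,
# structured per-stage logging and a JSON run manifest (config snapshot,
# output checksums, per-stage timings). Internal units are volts, seconds
# and micrometres throughout; conversion to mV/ms/mm happens only at
# reporting and at the speed-formula boundary.

#' Default pipeline configuration
#'
#' Defaults are the standard recording/analysis settings: 25 kHz sampling,
#' 200 Hz high-pass, 5 sigma threshold, 3 ms dead time, 16 ms STTH window
#' with 0.05 ms bins, five electrodes at 500 um pitch.
#'
#' @param seed master integer seed.
#' @return nested configuration list (sections `simulation`, `detection`,
#'   `stth`, `metrics`, `io`, plus `seed`).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(
      enabled = TRUE, sampling_rate_hz = 25000, duration_s = 60,
      firing_rate_hz = 5, conduction_speed_m_s = 0.5,
      spike_amplitude_v = 4e-4, noise_sigma_v = ptp_to_sigma(2e-4, 25000L),
      n_units = 1L, n_electrodes = 5L, pitch_um = 500),
    detection = list(cutoff_hz = 200, order = 4L, k = 5, dead_time_ms = 3),
    stth = list(window_ms = 16, bin_ms = 0.05, min_ref_spikes = 50, z = 3),
    metrics = list(aggregation = "mean", alpha = 0.05),
    io = list(recording_path = NULL, geometry_path = NULL,
              write_recording = FALSE))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and any value outside its operation's
#' preconditions; error messages name the offending key.
#'
#' @param config nested configuration list (see
#'   [default_pipeline_config()]).
#' @return the config, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  tmpl <- default_pipeline_config()
  bad <- setdiff(names(config), names(tmpl))
  if (length(bad) > 0L)
    stop_param(bad[1], "unknown configuration key")
  for (sec in c("simulation", "detection", "stth", "metrics", "io")) {
    unknown <- setdiff(names(config[[sec]]), names(tmpl[[sec]]))
    if (length(unknown) > 0L)
      stop_param(paste(sec, unknown[1], sep = "."), "unknown configuration key")
  }
  s <- config$simulation
  check_positive(s$sampling_rate_hz, "simulation.sampling_rate_hz")
  check_positive(s$duration_s, "simulation.duration_s")
  check_positive(s$firing_rate_hz, "simulation.firing_rate_hz")
  check_positive(s$conduction_speed_m_s, "simulation.conduction_speed_m_s")
  check_positive(s$spike_amplitude_v, "simulation.spike_amplitude_v")
  check_nonneg(s$noise_sigma_v, "simulation.noise_sigma_v")
  check_nonneg(s$n_units, "simulation.n_units")
  check_positive(s$pitch_um, "simulation.pitch_um")
  d <- config$detection
  check_positive(d$cutoff_hz, "detection.cutoff_hz")
  if (d$cutoff_hz >= s$sampling_rate_hz / 2)
    stop_param("detection.cutoff_hz", "must be below the Nyquist frequency")
  check_positive(d$order, "detection.order")
  check_positive(d$k, "detection.k")
  check_nonneg(d$dead_time_ms, "detection.dead_time_ms")
  st <- config$stth
  check_positive(st$window_ms, "stth.window_ms")
  check_positive(st$bin_ms, "stth.bin_ms")
  r <- st$window_ms / st$bin_ms
  if (abs(r - round(r)) > 1e-9 * r)
    stop_param("stth.window_ms", "must be an integer multiple of stth.bin_ms")
  check_nonneg(st$min_ref_spikes, "stth.min_ref_spikes")
  check_nonneg(st$z, "stth.z")
  if (!config$metrics$aggregation %in% c("mean", "sum", "max"))
    stop_param("metrics.aggregation", "must be one of mean, sum, max")
  check_positive(config$metrics$alpha, "metrics.alpha")
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop_param("seed", "must be a single integer")
  invisible(config)
}

#' @keywords internal
log_stage <- function(stage, ..., verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] %s", stage, paste0(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> detect -> conduction -> metrics, writes
#' every intermediate table as CSV into `out_dir`, and writes a JSON
#' manifest (`manifest.json`) with the config snapshot, md5 checksums of
#' all outputs, per-stage timings and output paths. The manifest is
#' written atomically (temp file + rename) at run end. A fixed seed makes
#' every CSV bit-identical across runs.
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @param out_dir output directory (created if missing).
#' @param verbose log one structured line per stage (default TRUE).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tick <- function() proc.time()[["elapsed"]]
  stage_wrap <- function(name, expr) {
    t0 <- tick()
    res <- tryCatch(expr, error = function(e) {
      manifest <- list(status = "failed", failed_stage = name,
                       error = conditionMessage(e), config = config,
                       timings_s = timings)
      write_manifest(manifest, out_dir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(tick() - t0, 3)
    res
  }

  # --- input stage: simulate or load -------------------------------------
  sim <- config$simulation
  if (isTRUE(sim$enabled)) {
    rec <- stage_wrap("simulate", {
      geometry <- if (!is.null(config$io$geometry_path))
        read_geometry(config$io$geometry_path)[[1]]
      else default_geometry("ch1", sim$n_electrodes, sim$pitch_um)
      cfg <- sim_config(sim$sampling_rate_hz, sim$duration_s,
                        sim$firing_rate_hz, sim$conduction_speed_m_s,
                        sim$spike_amplitude_v, sim$noise_sigma_v,
                        seed = config$seed)
      r <- if (sim$n_units >= 1L)
        simulate_recording(geometry, cfg, n_units = sim$n_units)
      else render_recording(list(), geometry, cfg)
      log_stage("simulate",
                sprintf("duration=%gs fs=%gHz electrodes=%d units=%d seed=%d",
                        sim$duration_s, sim$sampling_rate_hz,
                        length(geometry$electrode_ids), sim$n_units,
                        config$seed), verbose = verbose)
      if (isTRUE(config$io$write_recording))
        write_recording(r, file.path(out_dir, "recording"))
      attr(r, "geometry") <- geometry
      r
    })
    geometry <- attr(rec, "geometry")
  } else {
    rec <- stage_wrap("load", {
      if (is.null(config$io$recording_path))
        stop_param("io.recording_path", "required when simulation is disabled")
      read_recording(config$io$recording_path)
    })
    geometry <- stage_wrap("load_geometry", {
      if (is.null(config$io$geometry_path))
        stop_param("io.geometry_path", "required when simulation is disabled")
      read_geometry(config$io$geometry_path)[[1]]
    })
  }

  # --- detection ---------------------------------------------------------
  det <- config$detection
  trains <- stage_wrap("detect", {
    tr <- detect_recording(rec, det$cutoff_hz, det$order, det$k,
                           det$dead_time_ms / 1000)
    log_stage("detect",
              sprintf("cutoff=%gHz order=%d k=%g dead_time=%gms spikes=%d",
                      det$cutoff_hz, det$order, det$k, det$dead_time_ms,
                      sum(vapply(tr, function(s) length(s$times_s),
                                 integer(1)))), verbose = verbose)
    tr
  })
  spikes <- spikes_table(trains)
  utils::write.csv(spikes, file.path(out_dir, "spikes.csv"),
                   row.names = FALSE)

  # --- conduction --------------------------------------------------------
  st <- config$stth
  speeds <- stage_wrap("conduction", {
    sp <- estimate_conduction_speed(geometry, trains,
                                    window_s = st$window_ms / 1000,
                                    bin_s = st$bin_ms / 1000,
                                    min_ref_spikes = st$min_ref_spikes,
                                    z = st$z)
    log_stage("conduction",
              sprintf("window=%gms bin=%gms pairs=%d significant=%d",
                      st$window_ms, st$bin_ms, nrow(sp),
                      sum(sp$significant)), verbose = verbose)
    sp
  })
  utils::write.csv(speeds, file.path(out_dir, "speeds.csv"),
                   row.names = FALSE)
  summary_sp <- suppressMessages(channel_speed_summary(speeds))
  utils::write.csv(summary_sp, file.path(out_dir, "channel_speeds.csv"),
                   row.names = FALSE)

  # --- metrics -----------------------------------------------------------
  mfr <- stage_wrap("metrics", {
    m <- mean_firing_rate(trains, geometry, rec$duration_s,
                          aggregate = config$metrics$aggregation)
    log_stage("metrics",
              sprintf("aggregation=%s channels=%d",
                      config$metrics$aggregation, nrow(m$channels)),
              verbose = verbose)
    m
  })
  utils::write.csv(mfr$channels, file.path(out_dir, "mfr_channels.csv"),
                   row.names = FALSE)
  utils::write.csv(mfr$electrodes, file.path(out_dir, "mfr_electrodes.csv"),
                   row.names = FALSE)

  outputs <- c("spikes.csv", "speeds.csv", "channel_speeds.csv",
               "mfr_channels.csv", "mfr_electrodes.csv")
  paths <- file.path(out_dir, outputs)
  manifest <- list(status = "ok", config = config,
                   outputs = as.list(stats::setNames(paths, outputs)),
                   checksums = as.list(tools::md5sum(paths)),
                   timings_s = timings,
                   package_version = as.character(utils::packageVersion("axonmea")))
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

#' @keywords internal
write_manifest <- function(manifest, out_dir) {
  tmp <- tempfile(tmpdir = out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
}

#' Create a named test fixture
#'
#' Writes a geometry CSV and a config JSON for one of three canonical
#' scenarios: `tiny` (5 s, 2 electrodes — fast unit-test input), `recovery`
#' (600 s, 5 electrodes, 0.5 m/s — conduction-speed recovery) and `null`
#' (noise only — false-positive floor).
#'
#' @param name one of `"tiny"`, `"recovery"`, `"null"`.
#' @param seed master seed stored in the fixture config.
#' @param dir directory to create the fixture in.
#' @return the fixture directory, invisibly.
#' @export
make_fixture <- function(name, seed = 1L, dir = tempfile("fixture")) {
  if (!name %in% c("tiny", "recovery", "null"))
    stop_param("name", "must be one of tiny, recovery, null")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- default_pipeline_config(seed)
  if (name == "tiny") {
    cfg$simulation$duration_s <- 5
    cfg$simulation$n_electrodes <- 2L
  } else if (name == "recovery") {
    cfg$simulation$duration_s <- 600
    cfg$simulation$conduction_speed_m_s <- 0.5
  } else {
    cfg$simulation$n_units <- 0L
  }
  geometry <- default_geometry("ch1", cfg$simulation$n_electrodes,
                               cfg$simulation$pitch_um)
  write_geometry(geometry, file.path(dir, "geometry.csv"))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a fixture or pipeline config JSON
#'
#' @param path path to a config JSON written by [make_fixture()].
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  validate_pipeline_config(cfg)
  cfg
}
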