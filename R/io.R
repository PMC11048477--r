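#' Construct a CW-NIRS recording
#'
#' A recording holds the raw-worksheet data — a `time_s` column plus one
#' intensity column per (wavelength, separation) channel named as by
#' [channel_name()] — together with its acquisition metadata.
#'
#' @param data tibble with `time_s` (strictly increasing) and intensity
#'   columns
#' @param wavelengths wavelengths in nm
#' @param separations separations in cm
#' @param fs sampling rate, Hz
#' @param meta free-form metadata list
#' @export
nirs_recording <- function(data, wavelengths, separations, fs, meta = list()) {
  abort_if(!"time_s" %in% names(data), "data needs a time_s column")
  abort_if(nrow(data) == 0, "recording is empty")
  abort_if(any(diff(data$time_s) <= 0), "time_s must be strictly increasing")
  cols <- as.vector(outer(wavelengths, separations, channel_name))
  miss <- setdiff(cols, names(data))
  abort_if(length(miss) > 0, "missing intensity column(s): %s",
           paste(miss, collapse = ", "))
  structure(list(data = tibble::as_tibble(data),
                 wavelengths = as.numeric(wavelengths),
                 separations = as.numeric(separations),
                 fs = fs, meta = meta),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("CW-NIRS recording: %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat(sprintf("  wavelengths: %s nm | separations: %s cm\n",
              paste(x$wavelengths, collapse = "/"),
              paste(x$separations, collapse = "/")))
  invisible(x)
}

write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_header_field <- function(lines, key) {
  m <- grep(sprintf("^# %s:", key), lines, value = TRUE)
  if (length(m) == 0) return(NULL)
  trimws(sub(sprintf("^# %s:", key), "", m[1]))
}

#' Write a raw-data worksheet
#'
#' CSV mirroring the device app's raw worksheet: `time_s` plus
#' `i_{wavelength}nm_{separation}cm` intensity columns. Acquisition
#' parameters (sampling rate, wavelengths, separations) and, when supplied,
#' the seed and configuration hash go into `#` comment header lines.
#'
#' @param rec a [nirs_recording()]
#' @param path output CSV path
#' @param config optional [run_config()]; its hash is embedded
#' @export
write_raw_worksheet <- function(rec, path, config = NULL) {
  stopifnot(inherits(rec, "nirs_recording"))
  hdr <- c("cwnirs raw worksheet",
           sprintf("sampling_rate_hz: %g", rec$fs),
           sprintf("wavelengths_nm: %s", paste(rec$wavelengths, collapse = ",")),
           sprintf("separations_cm: %s", paste(rec$separations, collapse = ",")))
  if (!is.null(rec$meta$seed)) hdr <- c(hdr, sprintf("seed: %s", rec$meta$seed))
  if (!is.null(config)) hdr <- c(hdr, sprintf("config_hash: %s", config_hash(config)))
  write_csv_with_header(rec$data, path, hdr)
  invisible(path)
}

#' Read a raw-data worksheet
#'
#' Validates the schema (a `time_s` column plus `i_*` intensity columns) and
#' flags rows containing non-positive intensities without dropping them;
#' the flagged-row count is attached as attribute `n_flagged` and reported
#' with a warning.
#'
#' @param path CSV path written by [write_raw_worksheet()]
#' @export
read_raw_worksheet <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  lines <- readLines(path, n = 20)
  df <- utils::read.csv(path, comment.char = "#")
  abort_if(nrow(df) == 0, "empty raw worksheet: %s", path)
  icols <- grep("^i_\\d+nm_", names(df), value = TRUE)
  extra <- setdiff(names(df), c("time_s", icols))
  abort_if(!"time_s" %in% names(df) || length(icols) == 0,
           "schema mismatch in %s: need time_s and i_<wavelength>nm_<sep>cm columns%s",
           path,
           if (length(extra)) paste0(" (unexpected: ", paste(extra, collapse = ", "), ")") else "")
  abort_if(length(extra) > 0, "schema mismatch in %s: unexpected column(s) %s",
           path, paste(extra, collapse = ", "))
  fs <- as.numeric(read_header_field(lines, "sampling_rate_hz") %||%
                     (1 / stats::median(diff(df$time_s))))
  wl <- as.numeric(strsplit(read_header_field(lines, "wavelengths_nm") %||%
                              paste(sort(unique(as.numeric(sub("^i_(\\d+)nm_.*", "\\1", icols)))),
                                    collapse = ","), ",")[[1]])
  sp <- as.numeric(strsplit(read_header_field(lines, "separations_cm") %||%
                              paste(sort(unique(as.numeric(sub("^i_\\d+nm_([0-9.]+)cm$", "\\1", icols)))),
                                    collapse = ","), ",")[[1]])
  bad_rows <- which(apply(as.matrix(df[icols]) <= 0 | is.na(df[icols]), 1, any))
  if (length(bad_rows) > 0)
    warning(sprintf("%d row(s) with non-positive intensity flagged (e.g. line %d)",
                    length(bad_rows), bad_rows[1]), call. = FALSE)
  seed <- read_header_field(lines, "seed")
  rec <- nirs_recording(tibble::as_tibble(df), wl, sp, fs,
                        meta = list(seed = if (!is.null(seed)) as.numeric(seed)))
  attr(rec, "n_flagged") <- length(bad_rows)
  rec
}

PROCESSED_COLUMNS <- c("time_s", "d_hbo_3cm", "d_hb_3cm", "d_thb_3cm",
                       "d_hbo_4cm", "d_hb_4cm", "d_thb_4cm",
                       "sto2_srs", "sto2_ssds_3cm", "sto2_ssds_4cm")

#' Write a processed-data worksheet
#'
#' CSV mirroring the device app's processed worksheet: per-SDS hemoglobin
#' changes (uM) and the three StO2 traces (%). Columns absent from `df`
#' (e.g. SRS when only one separation was recorded) are written as `NA`.
#'
#' @param df processed tibble (subset of the canonical columns)
#' @param path output path
#' @param config optional [run_config()] whose hash is embedded
#' @export
write_processed_worksheet <- function(df, path, config = NULL) {
  out <- tibble::as_tibble(df)
  for (cl in setdiff(PROCESSED_COLUMNS, names(out))) out[[cl]] <- NA_real_
  out <- out[PROCESSED_COLUMNS]
  hdr <- "cwnirs processed worksheet"
  if (!is.null(config)) hdr <- c(hdr, sprintf("config_hash: %s", config_hash(config)))
  write_csv_with_header(out, path, hdr)
  invisible(path)
}

#' Read a processed-data worksheet
#' @param path CSV path written by [write_processed_worksheet()]
#' @export
read_processed_worksheet <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(PROCESSED_COLUMNS, names(df))
  abort_if(length(miss) > 0, "schema mismatch in %s: missing column(s) %s",
           path, paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write the ground-truth sidecar of a simulation
#'
#' JSON document holding every generating parameter (tissue, scenario,
#' noise, instrument, mode, seed, true calibration ratios, spike times) —
#' sufficient to recompute all intermediate quantities of the simulation.
#'
#' @param sim an object from [simulate_recording()]
#' @param path output JSON path
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "nirs_simulation"))
  tr <- sim$truth
  doc <- list(mode = tr$mode, seed = tr$seed,
              duration_s = nrow(sim$recording$data) / sim$recording$fs,
              k = as.list(tr$k), spike_times = tr$spike_times,
              tissue = unclass(tr$tissue), scenario = unclass(tr$scenario),
              noise = unclass(tr$noise), instrument = unclass(tr$instrument))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a ground-truth sidecar and rebuild the simulation
#'
#' Re-runs the generator from the stored parameters and seed, reproducing
#' the recording and every intermediate quantity bit-identically.
#'
#' @param path sidecar JSON path
#' @return an `nirs_simulation`
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tissue <- do.call(tissue_model, doc$tissue[c("sto2", "thb", "musp", "n_ref", "coupling_od")])
  sc <- doc$scenario
  scenario <- breath_hold_scenario(sc$t_onset, sc$hold_s, sc$dip_time, sc$peak_time,
                                   sc$recovery_tau, sc$dip_tau, sc$hbo_dip, sc$hbo_peak,
                                   sc$sto2_dip, sc$sto2_peak, preset = sc$preset)
  nz <- doc$noise
  noise <- noise_model(nz$white_sd, nz$cardiac_amp, nz$cardiac_freq, nz$resp_amp,
                       nz$resp_freq, nz$mayer_amp, nz$mayer_freq, nz$drift_sd_per_s,
                       nz$spike_rate, nz$spike_amp, nz$spike_times, nz$longhold_amp,
                       nz$longhold_freq, nz$longhold_threshold, nz$seed)
  ins <- doc$instrument
  instrument <- instrument_model(ins$wavelengths, ins$separations, ins$fs,
                                 ins$source_power, ins$detector_gain, ins$dpf)
  simulate_recording(tissue, scenario, noise, instrument,
                     mode = doc$mode, duration_s = doc$duration_s,
                     seed = doc$seed)
}

#' Write a simulated group dataset to a directory
#'
#' One raw worksheet plus ground-truth sidecar per recording and a
#' `manifest.csv` (subject, trial, onset, hold duration, per-recording
#' seed, file paths).
#'
#' @param group an object from [simulate_group()]
#' @param dir output directory (created if needed)
#' @param config optional [run_config()] embedded in the worksheets
#' @return the manifest tibble (invisibly)
#' @export
write_group <- function(group, dir, config = NULL) {
  stopifnot(inherits(group, "nirs_group"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- group$manifest
  man$raw_path <- sprintf("sub%02d_trial%d_raw.csv", man$subject_id, man$trial_id)
  man$truth_path <- sprintf("sub%02d_trial%d_truth.json", man$subject_id, man$trial_id)
  for (i in seq_len(nrow(man))) {
    write_raw_worksheet(group$recordings[[i]]$recording,
                        file.path(dir, man$raw_path[i]), config = config)
    write_ground_truth(group$recordings[[i]], file.path(dir, man$truth_path[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with its package default; values
#' are validated here, and [config_hash()] fingerprints the configuration
#' for embedding in output artifacts.
#'
#' @param wavelengths,separations probe geometry
#' @param fs sampling rate, Hz
#' @param dpf common differential pathlength factor
#' @param extinction_path path to an extinction CSV (`NULL` = packaged table)
#' @param calibration_method SSDS k-calibration method
#' @param musp assumed reduced scattering for SRS, cm^-1
#' @param window_s,range_s statistics windowing
#' @param snr_threshold SNR-screen threshold
#' @param seed RNG seed
#' @export
run_config <- function(wavelengths = c(730, 800, 850), separations = c(3, 4),
                       fs = 120, dpf = 6, extinction_path = NULL,
                       calibration_method = "source_spec", musp = 10,
                       window_s = 5, range_s = c(-5, 45),
                       snr_threshold = 100, seed = NULL) {
  abort_if(fs <= 0 || dpf <= 0 || window_s <= 0, "rates and factors must be positive")
  abort_if(diff(range_s) <= 0 || (diff(range_s) %% window_s) != 0,
           "range must span a whole number of windows")
  structure(list(wavelengths = wavelengths, separations = separations, fs = fs,
                 dpf = dpf, extinction_path = extinction_path,
                 calibration_method = calibration_method, musp = musp,
                 window_s = window_s, range_s = range_s,
                 snr_threshold = snr_threshold, seed = seed),
            class = "cwnirs_config")
}

#' Fingerprint of a configuration
#' @param config a [run_config()]
#' @export
config_hash <- function(config) rlang::hash(unclass(config))
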