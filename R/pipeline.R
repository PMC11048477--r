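#' Process a raw recording into the processed-worksheet quantities
#'
#' Computes, per available separation, the MBLL hemoglobin-change traces and
#' the SSDS StO2 trace, and — when both separations are present — the SRS
#' StO2 trace. A recording missing the far channels degrades gracefully:
#' SSDS at 3 cm is still computed and SRS is skipped with a message.
#'
#' @param rec a [nirs_recording()]
#' @param cal an [ssds_calibration()]; required for the SSDS columns
#' @param onset task onset time (s), used for the MBLL reference epoch
#' @param config a [run_config()]
#' @return processed tibble in the canonical column layout (see
#'   [write_processed_worksheet()]), with absent quantities as `NA`
#' @export
process_recording <- function(rec, cal, onset = NULL, config = run_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  table <- extinction_table(config$extinction_path)
  dpf <- equal_dpf(config$dpf)
  out <- tibble::tibble(time_s = rec$data$time_s)
  for (sep in rec$separations) {
    tag <- sprintf("%gcm", sep)
    mb <- mbll_timeseries(rec, sep, onset = onset, dpf = dpf, table = table)
    out[[paste0("d_hbo_", tag)]] <- mb$d_hbo
    out[[paste0("d_hb_", tag)]] <- mb$d_hb
    out[[paste0("d_thb_", tag)]] <- mb$d_thb
    ss <- ssds_timeseries(rec, sep, cal, dpf = dpf, table = table)
    out[[paste0("sto2_ssds_", tag)]] <- ss$sto2
  }
  if (length(unique(rec$separations)) == 2) {
    out$sto2_srs <- srs_timeseries(rec, musp = config$musp, table = table)$sto2
  } else {
    message("single-separation recording: SRS StO2 skipped")
    out$sto2_srs <- NA_real_
  }
  out
}

#' Process every recording of a simulated group
#'
#' Uses each simulation's true source-intensity ratios for the SSDS
#' calibration (the `source_spec` method) and the manifest onsets for the
#' MBLL reference epochs.
#'
#' @param group an object from [simulate_group()]
#' @param config a [run_config()]
#' @return list of processed tibbles, parallel to `group$recordings`
#' @export
process_group <- function(group, config = run_config()) {
  stopifnot(inherits(group, "nirs_group"))
  lapply(seq_along(group$recordings), function(i) {
    sim <- group$recordings[[i]]
    cal <- ssds_calibration(sim$truth$k[["k1"]], sim$truth$k[["k2"]])
    process_recording(sim$recording, cal,
                      onset = group$manifest$onset_s[i], config = config)
  })
}

# Signals extracted from a processed worksheet for group statistics.
ANALYSIS_SIGNALS <- c(hbo_3cm = "d_hbo_3cm", hbo_4cm = "d_hbo_4cm",
                      sto2_srs = "sto2_srs", sto2_ssds_3cm = "sto2_ssds_3cm",
                      sto2_ssds_4cm = "sto2_ssds_4cm")

#' Build the baseline-subtracted window table for a set of processed trials
#'
#' Epochs each signal of each trial into 5-s window means relative to its
#' onset and subtracts the baseline (-5 to 0 s) window. Signals that are
#' entirely missing from a trial (e.g. SRS in a single-separation
#' recording) are omitted for that trial.
#'
#' @param processed list of processed tibbles
#' @param onsets numeric vector of task onsets, one per trial
#' @param config a [run_config()]
#' @param signals named character vector mapping signal ids to processed
#'   columns
#' @return long tibble `trial`, `signal`, `window_start`, `value`
#' @export
window_table <- function(processed, onsets, config = run_config(),
                         signals = ANALYSIS_SIGNALS) {
  abort_if(length(processed) != length(onsets),
           "need one onset per processed trial")
  rows <- list()
  for (i in seq_along(processed)) {
    p <- processed[[i]]
    for (sg in names(signals)) {
      col <- signals[[sg]]
      if (!col %in% names(p) || all(is.na(p[[col]]))) next
      w <- epoch_windows(p$time_s, p[[col]], onset = onsets[i],
                         window_s = config$window_s, range_s = config$range_s)
      w <- baseline_subtract(w, baseline_start = config$range_s[1])
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial = i, signal = sg, window_start = w$window_start, value = w$mean)
    }
  }
  do.call(rbind, rows)
}

#' Simulate, process and analyse a full breath-hold study
#'
#' Convenience wrapper chaining [simulate_group()], [process_group()],
#' [window_table()] and [group_analysis()].
#'
#' @param seed master seed
#' @param config a [run_config()]
#' @param ... passed to [simulate_group()]
#' @return list `group`, `processed`, `windows`, `report`
#' @export
run_breath_hold_study <- function(seed = NULL, config = run_config(), ...) {
  group <- simulate_group(seed = seed, ...)
  processed <- process_group(group, config)
  windows <- window_table(processed, group$manifest$onset_s, config)
  report <- group_analysis(windows)
  list(group = group, processed = processed, windows = windows, report = report)
}

#' Bar plot of group window means with standard errors
#'
#' The canonical summary figure of a breath-hold analysis: baseline-
#' subtracted 5-s window means +/- SE for one signal.
#'
#' @param report a `bh_stat_report` from [group_analysis()]
#' @param signal which signal to plot
#' @return a ggplot object
#' @export
plot_window_means <- function(report, signal) {
  s <- report$summary[report$summary$signal == signal, ]
  abort_if(nrow(s) == 0, "no such signal: %s", signal)
  mid <- (s$window_start + s$window_start + 5) / 2
  ggplot2::ggplot(tibble::tibble(mid = mid, mean = s$mean, se = s$se),
                  ggplot2::aes(x = mid, y = mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 4) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - se, ymax = mean + se),
                           width = 1.5) +
    ggplot2::labs(x = "time from task onset (s), 5-s windows",
                  y = sprintf("%s change (baseline-subtracted)", signal)) +
    ggplot2::theme_minimal()
}

#' Single-trial StO2 traces with task markers
#'
#' Overlays the SRS and SSDS StO2 traces of one processed trial with
#' vertical markers at task onset and end.
#'
#' @param processed one processed tibble
#' @param onset,hold_s task onset and hold duration, s
#' @return a ggplot object
#' @export
plot_sto2_traces <- function(processed, onset, hold_s) {
  cols <- intersect(c("sto2_srs", "sto2_ssds_3cm", "sto2_ssds_4cm"),
                    names(processed))
  long <- do.call(rbind, lapply(cols, function(cl)
    tibble::tibble(time_s = processed$time_s, sto2 = processed[[cl]], method = cl)))
  ggplot2::ggplot(long, ggplot2::aes(x = time_s, y = sto2, colour = method)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(onset, onset + hold_s), linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "StO2 (%)") +
    ggplot2::theme_minimal()
}
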