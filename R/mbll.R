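#' Attenuation change relative to a reference intensity
#'
#' Delta A = -log10(I_t / I_ref), in optical density (OD, base-10). Samples
#' with non-positive measured intensity are flagged: they come back as `NA`
#' with their indices in attribute `"flagged"` rather than being dropped.
#'
#' @param i_t measured intensity (vector), arbitrary linear units
#' @param i_ref reference intensity (scalar or vector), same units
#' @return numeric vector of Delta A with attribute `flagged`
#' @export
attenuation_change <- function(i_t, i_ref) {
  abort_if(!is.numeric(i_t) || !is.numeric(i_ref), "intensities must be numeric")
  abort_if(anyNA(i_ref) || any(i_ref <= 0), "reference intensity must be positive")
  bad <- which(!is.finite(i_t) | i_t <= 0)
  dA <- rep(NA_real_, length(i_t))
  ok <- setdiff(seq_along(i_t), bad)
  if (length(i_ref) > 1) {
    dA[ok] <- -log10(i_t[ok] / i_ref[ok])
  } else {
    dA[ok] <- -log10(i_t[ok] / i_ref)
  }
  attr(dA, "flagged") <- bad
  dA
}

#' Hemoglobin concentration changes via the modified Beer-Lambert law
#'
#' Solves Delta A(lambda) = d * DPF(lambda) * (eps_HbO(lambda) * dC_HbO +
#' eps_Hb(lambda) * dC_Hb) by least squares over the wavelengths (an
#' overdetermined 3-wavelength solve by default, using all channels
#' symmetrically).
#'
#' @param dA matrix (samples x wavelengths) of attenuation changes in OD,
#'   or a vector for a single sample
#' @param dpf a [dpf_set()]
#' @param separation source-detector distance d in cm
#' @param table an [extinction_table()]
#' @param wavelengths wavelengths of the columns of `dA`
#' @return tibble with columns `d_hbo`, `d_hb`, `d_thb` (uM)
#' @export
mbll_changes <- function(dA, dpf = equal_dpf(), separation,
                         table = extinction_table(),
                         wavelengths = table$wavelength_nm) {
  if (is.null(dim(dA))) dA <- matrix(dA, nrow = 1)
  abort_if(ncol(dA) != length(wavelengths),
           "dA has %d columns but %d wavelengths given", ncol(dA), length(wavelengths))
  abort_if(length(dpf) != length(wavelengths), "need one DPF per wavelength")
  abort_if(separation <= 0, "separation must be positive")
  E <- extinction_matrix(table, wavelengths)
  M <- separation * diag(as.numeric(dpf), nrow = length(dpf)) %*% E
  abort_if(kappa(M, exact = TRUE) > 1e8, "singular extinction system")
  ok <- stats::complete.cases(dA)
  dc <- matrix(NA_real_, 2, nrow(dA))
  if (any(ok)) dc[, ok] <- qr.coef(qr(M), t(dA[ok, , drop = FALSE]))
  tibble::tibble(d_hbo = dc[1, ], d_hb = dc[2, ], d_thb = dc[1, ] + dc[2, ])
}

#' MBLL concentration-change trace for one separation of a recording
#'
#' Reference intensity is the per-channel mean over a reference epoch
#' (default: the 5 s immediately before task onset, the same convention the
#' breath-hold statistics use for their baseline). Flagged (non-positive)
#' samples are interpolated only across gaps no longer than `max_gap_s`;
#' longer gaps stay missing.
#'
#' @param rec a [nirs_recording()]
#' @param separation which source-detector separation (cm) to process
#' @param onset task onset time (s); used for the default reference epoch
#' @param ref_epoch length-2 vector `c(t0, t1)` over which the reference
#'   intensity is averaged; default `c(onset - 5, onset)`, or the first 5 s
#'   when no onset is given
#' @param dpf,table,wavelengths forwarded to [mbll_changes()]
#' @param max_gap_s maximum flagged-gap duration (s) to interpolate
#' @return tibble `time_s`, `d_hbo`, `d_hb`, `d_thb`, with attribute
#'   `n_flagged` (number of flagged samples per wavelength)
#' @export
mbll_timeseries <- function(rec, separation, onset = NULL, ref_epoch = NULL,
                            dpf = equal_dpf(), table = extinction_table(),
                            wavelengths = rec$wavelengths, max_gap_s = 0.5) {
  stopifnot(inherits(rec, "nirs_recording"))
  abort_if(!separation %in% rec$separations,
           "recording has no channels at %g cm", separation)
  t <- rec$data$time_s
  if (is.null(ref_epoch)) {
    ref_epoch <- if (is.null(onset)) c(t[1], t[1] + 5) else c(onset - 5, onset)
  }
  in_ref <- t >= ref_epoch[1] & t < ref_epoch[2]
  abort_if(!any(in_ref), "reference epoch [%g, %g) contains no samples",
           ref_epoch[1], ref_epoch[2])
  cols <- channel_name(wavelengths, separation)
  abort_if(!all(cols %in% names(rec$data)), "missing channel(s): %s",
           paste(setdiff(cols, names(rec$data)), collapse = ", "))
  I <- as.matrix(rec$data[cols])
  max_gap <- floor(max_gap_s * rec$fs)
  n_flagged <- integer(length(cols))
  dA <- matrix(NA_real_, nrow(I), ncol(I))
  for (j in seq_along(cols)) {
    pos <- I[, j] > 0 & is.finite(I[, j])
    i_ref <- mean(I[in_ref & pos, j])
    abort_if(!is.finite(i_ref) || i_ref <= 0,
             "no valid reference samples for channel %s", cols[j])
    a <- attenuation_change(I[, j], i_ref)
    n_flagged[j] <- length(attr(a, "flagged"))
    dA[, j] <- fill_short_gaps(as.numeric(a), max_gap)
  }
  out <- mbll_changes(dA, dpf = dpf, separation = separation,
                      table = table, wavelengths = wavelengths)
  out <- tibble::add_column(out, time_s = t, .before = 1)
  attr(out, "n_flagged") <- stats::setNames(n_flagged, cols)
  out
}
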