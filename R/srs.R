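#' Spatial slope of attenuation between two separations
#'
#' Converts the optical-density difference across the two source-detector
#' separations into a natural-log attenuation slope:
#' slope = ln(10) * (A(rho2) - A(rho1)) / (rho2 - rho1), in cm^-1.
#'
#' @param a1,a2 attenuation (OD, base-10) at the near and far separation;
#'   vectors allowed
#' @param rho1,rho2 separations in cm, `rho2 > rho1 > 0`
#' @return numeric slope(s), ln-units per cm
#' @export
attenuation_slope <- function(a1, a2, rho1, rho2) {
  abort_if(rho1 <= 0 || rho2 <= 0, "separations must be positive")
  abort_if(rho2 == rho1, "separations must differ")
  log(10) * (a2 - a1) / (rho2 - rho1)
}

#' Scaled absorption from the SRS diffusion asymptote
#'
#' In the semi-infinite diffusion asymptote the attenuation slope is
#' approximately mu_eff + 2/rho, with mu_eff = sqrt(3 mu_a mu_s'). Removing
#' the geometric 2/rho term at the mean separation and squaring yields an
#' absorption estimate up to the mu_s' assumption:
#' mu_a ~ (slope - 2/mean_rho)^2 / (3 mu_s'(lambda)).
#' A common scale error in mu_s' across wavelengths cancels in the
#' downstream StO2. Samples with slope <= 2/mean_rho have no valid estimate
#' and come back `NA` (flag the sample, don't invent a value).
#'
#' @param slope slope(s) from [attenuation_slope()]; vector or matrix
#'   (samples x wavelengths)
#' @param mean_rho mean separation in cm (device default 3.5)
#' @param musp assumed reduced scattering coefficient(s), cm^-1, recycled
#'   across columns
#' @return relative mu_a, same shape as `slope`, `NA` where invalid
#' @export
srs_scaled_absorption <- function(slope, mean_rho, musp) {
  abort_if(mean_rho <= 0, "mean_rho must be positive")
  abort_if(any(musp <= 0), "musp must be positive")
  excess <- slope - 2 / mean_rho
  out <- ifelse(excess > 0, excess^2, NA_real_)
  if (is.matrix(slope)) out <- sweep(out, 2, 3 * musp, "/") else out <- out / (3 * musp)
  out
}

#' StO2 from relative absorption spectra (SRS)
#'
#' Solves the two-chromophore system on the relative mu_a vector; the common
#' scale factor cancels in StO2 = 100 HbO/(HbO + Hb).
#'
#' @param mu_rel relative absorption; vector (one sample) or matrix
#'   (samples x wavelengths)
#' @param table an [extinction_table()]
#' @param wavelengths wavelengths of the columns of `mu_rel`
#' @return numeric StO2 (%), `NA` where any wavelength was invalid
#' @export
srs_sto2 <- function(mu_rel, table = extinction_table(),
                     wavelengths = table$wavelength_nm) {
  if (is.null(dim(mu_rel))) mu_rel <- matrix(mu_rel, nrow = 1)
  sto2 <- rep(NA_real_, nrow(mu_rel))
  ok <- stats::complete.cases(mu_rel)
  if (any(ok)) {
    st <- solve_two_chromophores(mu_rel[ok, , drop = FALSE], table, wavelengths)
    sto2[ok] <- st$sto2
  }
  sto2
}

#' SRS StO2 time series from a two-separation recording
#'
#' Per-sample spatially resolved spectroscopy estimate: per-wavelength
#' attenuation at both separations, spatial slope, scaled absorption, then
#' the two-chromophore solve. Because only the intensity *ratio* between
#' separations enters, the estimate is invariant to any source-power drift
#' common to all channels. Invalid samples (non-positive intensity or slope
#' at or below 2/mean_rho at any wavelength) are flagged, not interpolated.
#'
#' @param rec a [nirs_recording()] with both separations
#' @param musp assumed mu_s' per wavelength (cm^-1), scalar recycled
#' @param mean_rho mean separation; default the arithmetic mean of the two
#' @param gain_ratio relative gain of the far vs the near detector (default
#'   1); the far-channel intensities are divided by it before use. A wrong
#'   value biases the slope by log10(gain_ratio)/(rho2-rho1) per cm.
#' @param table an [extinction_table()]
#' @return StO2 trace tibble `time_s`, `sto2`, `flag_invalid_sample`, with
#'   attribute `method = "srs"`
#' @export
srs_timeseries <- function(rec, musp = 10, mean_rho = NULL, gain_ratio = 1,
                           table = extinction_table()) {
  stopifnot(inherits(rec, "nirs_recording"))
  seps <- sort(unique(rec$separations))
  abort_if(length(seps) != 2, "SRS requires a recording with exactly two separations")
  abort_if(gain_ratio <= 0, "gain_ratio must be positive")
  mean_rho <- mean_rho %||% mean(seps)
  musp <- rep_len(musp, length(rec$wavelengths))
  near <- as.matrix(rec$data[channel_name(rec$wavelengths, seps[1])])
  far <- as.matrix(rec$data[channel_name(rec$wavelengths, seps[2])]) / gain_ratio
  valid <- is.finite(near) & near > 0 & is.finite(far) & far > 0
  a1 <- suppressWarnings(-log10(near))
  a2 <- suppressWarnings(-log10(far))
  a1[!valid] <- NA_real_; a2[!valid] <- NA_real_
  slope <- attenuation_slope(a1, a2, seps[1], seps[2])
  mu_rel <- srs_scaled_absorption(slope, mean_rho, musp)
  sto2 <- srs_sto2(mu_rel, table, rec$wavelengths)
  out <- tibble::tibble(time_s = rec$data$time_s, sto2 = sto2,
                        flag_invalid_sample = is.na(sto2))
  attr(out, "method") <- "srs"
  out
}
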