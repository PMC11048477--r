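#' SSDS calibration constants
#'
#' `k1` and `k2` are the emitted-intensity ratios of the source between
#' wavelengths: k1 = I0(lambda1)/I0(lambda2), k2 = I0(lambda3)/I0(lambda2).
#' Under this reading each log term of the SSDS formula is a pairwise
#' attenuation difference between wavelengths, and the estimator is
#' algebraically exact for the two-chromophore, equal-DPF model with
#' wavelength-independent coupling loss (see the methods vignette for the
#' cancellation).
#'
#' @param k1,k2 positive dimensionless ratios
#' @export
ssds_calibration <- function(k1, k2) {
  abort_if(!is.numeric(k1) || !is.numeric(k2) || length(k1) != 1 || length(k2) != 1,
           "k1 and k2 must be scalars")
  abort_if(!is.finite(k1) || !is.finite(k2) || k1 <= 0 || k2 <= 0,
           "k1 and k2 must be positive")
  structure(list(k1 = as.numeric(k1), k2 = as.numeric(k2)),
            class = "ssds_calibration")
}

#' Pairwise attenuation differences of the SSDS formula
#'
#' The three log terms, grouped as
#' A12 = log(k1 I2 / I1), A32 = log(k2 I2 / I3), A31 = log(k2 I1 / (k1 I3)).
#' The formula's numerator uses +A31 and its denominator the exact negative
#' -A31 = log(k1 I3 / (k2 I1)). Logarithms are base-10 by default; the SSDS
#' ratio is log-base invariant, so `base` only rescales all three terms.
#'
#' @param i1,i2,i3 detected intensities at the three wavelengths (vectors ok)
#' @param cal an [ssds_calibration()]
#' @param base logarithm base (10 or `exp(1)`)
#' @return list with numeric components `a12`, `a32`, `a31`
#' @export
pairwise_attenuation_differences <- function(i1, i2, i3, cal, base = 10) {
  abort_if(any(!is.finite(i1) | i1 <= 0) || any(!is.finite(i2) | i2 <= 0) ||
             any(!is.finite(i3) | i3 <= 0), "intensities must be positive")
  stopifnot(inherits(cal, "ssds_calibration"))
  lb <- function(x) log(x, base = base)
  list(a12 = lb(cal$k1 * i2 / i1),
       a32 = lb(cal$k2 * i2 / i3),
       a31 = lb(cal$k2 * i1 / (cal$k1 * i3)))
}

# Core SSDS evaluation on precomputed log terms. eps is the 3x2 extinction
# matrix (rows = wavelengths 1..3, cols = HbO, Hb).
ssds_eval <- function(a12, a32, a31, dpf, eps) {
  hb <- eps[, 2]; dhbo <- eps[, 1] - eps[, 2]
  num <- dpf[3] * a12 * hb[3] - dpf[1] * a32 * hb[1] + dpf[2] * a31 * hb[2]
  den <- dpf[1] * a32 * dhbo[1] - dpf[3] * a12 * dhbo[3] + dpf[2] * (-a31) * dhbo[2]
  list(num = num, den = den)
}

#' Absolute StO2 from a single source-detector pair (SSDS)
#'
#' Evaluates the three-wavelength SSDS formula: the ratio of two linear
#' combinations of pairwise attenuation differences weighted by DPFs and
#' extinction coefficients, times 100. Values are reported unclamped; QC
#' flags mark samples whose denominator is near zero (StO2 set to `NA`,
#' never a fabricated number) and samples outside the physiological
#' 0-100 % range.
#'
#' @param intensities numeric vector of length 3 (one sample) or matrix
#'   (samples x 3) with columns ordered lambda1, lambda2, lambda3
#' @param cal an [ssds_calibration()]
#' @param dpf a [dpf_set()]
#' @param table an [extinction_table()]
#' @param wavelengths the three wavelengths, increasing
#' @param den_tol absolute denominator tolerance (log-OD x extinction units)
#' @return tibble with columns `sto2` (%) and logical QC flags
#'   `flag_denominator_near_zero`, `flag_out_of_physio_range`,
#'   `flag_nonpositive_intensity`
#' @export
ssds_sto2 <- function(intensities, cal, dpf = equal_dpf(),
                      table = extinction_table(),
                      wavelengths = wavelength_triple(), den_tol = 1e-12) {
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  abort_if(ncol(intensities) != 3, "SSDS needs intensities at exactly 3 wavelengths")
  eps <- extinction_matrix(table, wavelengths)
  n <- nrow(intensities)
  sto2 <- rep(NA_real_, n)
  bad_i <- !stats::complete.cases(intensities) |
    apply(intensities <= 0, 1, any)
  near0 <- rep(FALSE, n)
  ok <- !bad_i
  if (any(ok)) {
    A <- pairwise_attenuation_differences(intensities[ok, 1], intensities[ok, 2],
                                          intensities[ok, 3], cal)
    v <- ssds_eval(A$a12, A$a32, A$a31, as.numeric(dpf), eps)
    nz <- abs(v$den) <= den_tol
    s <- ifelse(nz, NA_real_, 100 * v$num / v$den)
    sto2[ok] <- s
    near0[ok] <- nz
  }
  tibble::tibble(
    sto2 = sto2,
    flag_denominator_near_zero = near0,
    flag_out_of_physio_range = !is.na(sto2) & (sto2 < 0 | sto2 > 100),
    flag_nonpositive_intensity = bad_i
  )
}

#' SSDS StO2 time series for one separation of a recording
#'
#' Per-sample SSDS evaluation with QC flags; flagged samples are reported as
#' `NA` and neighbouring samples are unaffected. Optional moving-average
#' smoothing (off by default).
#'
#' @param rec a [nirs_recording()]
#' @param separation source-detector separation (cm) to use
#' @param cal an [ssds_calibration()]
#' @param dpf,table,den_tol forwarded to [ssds_sto2()]
#' @param smooth_window_s moving-average window in seconds (0 = off)
#' @return an StO2 trace: tibble `time_s`, `sto2`, QC flag columns, with
#'   attribute `method`
#' @export
ssds_timeseries <- function(rec, separation, cal, dpf = equal_dpf(),
                            table = extinction_table(), den_tol = 1e-12,
                            smooth_window_s = 0) {
  stopifnot(inherits(rec, "nirs_recording"))
  cols <- channel_name(rec$wavelengths, separation)
  miss <- setdiff(cols, names(rec$data))
  abort_if(length(miss) > 0, "recording is missing channel(s): %s",
           paste(miss, collapse = ", "))
  I <- as.matrix(rec$data[cols])
  out <- ssds_sto2(I, cal, dpf = dpf, table = table,
                   wavelengths = rec$wavelengths, den_tol = den_tol)
  if (smooth_window_s > 0) {
    w <- max(1L, round(smooth_window_s * rec$fs))
    k <- rep(1 / w, w)
    s <- out$sto2
    s[is.na(s)] <- stats::median(s, na.rm = TRUE)
    out$sto2 <- as.numeric(stats::filter(s, k, sides = 2))
  }
  out <- tibble::add_column(out, time_s = rec$data$time_s, .before = 1)
  attr(out, "method") <- sprintf("ssds_%gcm", separation)
  out
}

#' Estimate the SSDS calibration ratios k1, k2
#'
#' Two methods:
#' * `source_spec`: the declared emitted-intensity ratios of the source are
#'   used directly (pass `source_ratios = c(k1, k2)`).
#' * `baseline_assumed_sto2`: k1, k2 are chosen so that the SSDS formula
#'   evaluated on the baseline-epoch mean intensities reproduces an assumed
#'   baseline state (StO2, THb). Under the single-exponential attenuation
#'   model this gives k1 = (I1/I2) 10^(L (mu_a1 - mu_a2)) and
#'   k2 = (I3/I2) 10^(L (mu_a3 - mu_a2)) with L = DPF x d; if the assumed
#'   StO2 differs from the truth the estimated StO2 acquires a systematic,
#'   monotone offset (see vignette).
#'
#' @param rec a [nirs_recording()]
#' @param method `"source_spec"` or `"baseline_assumed_sto2"`
#' @param separation separation whose channels are used (baseline method)
#' @param source_ratios numeric `c(k1, k2)` for `source_spec`
#' @param baseline_epoch `c(t0, t1)` seconds (baseline method); default the
#'   first 5 s of the recording
#' @param assumed_sto2,assumed_thb assumed baseline state (%, uM)
#' @param dpf,table forwarded optical assumptions
#' @param min_epoch_s minimum admissible baseline-epoch length (s)
#' @return an [ssds_calibration()]
#' @export
calibrate_k <- function(rec, method = c("source_spec", "baseline_assumed_sto2"),
                        separation = NULL, source_ratios = NULL,
                        baseline_epoch = NULL, assumed_sto2 = 70,
                        assumed_thb = 60, dpf = equal_dpf(),
                        table = extinction_table(), min_epoch_s = 1) {
  method <- match.arg(method)
  if (method == "source_spec") {
    abort_if(is.null(source_ratios) || length(source_ratios) != 2,
             "source_spec calibration needs source_ratios = c(k1, k2)")
    return(ssds_calibration(source_ratios[1], source_ratios[2]))
  }
  stopifnot(inherits(rec, "nirs_recording"))
  abort_if(is.null(separation), "baseline calibration needs a separation")
  t <- rec$data$time_s
  baseline_epoch <- baseline_epoch %||% c(t[1], t[1] + 5)
  abort_if(diff(baseline_epoch) < min_epoch_s,
           "baseline epoch shorter than %g s", min_epoch_s)
  sel <- t >= baseline_epoch[1] & t < baseline_epoch[2]
  abort_if(sum(sel) < 2, "baseline epoch contains too few samples")
  cols <- channel_name(rec$wavelengths, separation)
  I <- colMeans(as.matrix(rec$data[sel, cols]))
  abort_if(any(I <= 0), "non-positive baseline mean intensity")
  state <- chromophore_state(assumed_sto2 / 100 * assumed_thb,
                             (1 - assumed_sto2 / 100) * assumed_thb)
  mua <- as.numeric(absorption_from_state(state, table, rec$wavelengths))
  L <- as.numeric(dpf) * separation
  k1 <- (I[1] / I[2]) * 10^(L[1] * mua[1] - L[2] * mua[2])
  k2 <- (I[3] / I[2]) * 10^(L[3] * mua[3] - L[2] * mua[2])
  ssds_calibration(k1, k2)
}
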