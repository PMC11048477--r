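#' Homogeneous tissue forward model
#'
#' Baseline optical state of the synthetic forehead: a chromophore baseline
#' (default StO2 70 %, THb 60 uM — a conventional resting cerebral state),
#' reduced scattering per wavelength, refractive index, and a
#' wavelength-shared coupling loss per separation (probe-contact loss in OD;
#' ratio-based estimators cancel it).
#'
#' @param sto2 baseline tissue oxygen saturation, %
#' @param thb baseline total hemoglobin, uM
#' @param musp reduced scattering coefficient(s) cm^-1, recycled to the
#'   three wavelengths
#' @param n_ref refractive index
#' @param coupling_od named or positional coupling losses (OD), one per
#'   separation
#' @export
tissue_model <- function(sto2 = 70, thb = 60, musp = 10, n_ref = 1.4,
                         coupling_od = c(0, 0)) {
  abort_if(thb <= 0, "THb must be positive")
  abort_if(sto2 < 0 || sto2 > 100, "baseline StO2 must be in [0, 100]")
  abort_if(any(musp <= 0), "musp must be positive")
  structure(list(sto2 = sto2, thb = thb, musp = rep_len(musp, 3),
                 n_ref = n_ref, coupling_od = coupling_od),
            class = "tissue_model")
}

#' Instrument model
#'
#' Wavelengths, separations, sampling rate, per-wavelength emitted source
#' power (arbitrary units; their ratios are the true SSDS k constants),
#' per-detector gain, and the DPF used by the single-exponential generator
#' mode.
#'
#' @param wavelengths wavelengths in nm
#' @param separations source-detector separations in cm
#' @param fs sampling rate in Hz (device default 120)
#' @param source_power emitted intensity per wavelength, arbitrary units
#' @param detector_gain linear gain per detector
#' @param dpf differential pathlength factor of the mbll-exact mode
#' @export
instrument_model <- function(wavelengths = wavelength_triple(),
                             separations = c(3, 4), fs = 120,
                             source_power = c(1.0, 0.9, 1.1),
                             detector_gain = c(1, 1), dpf = 6) {
  abort_if(fs <= 0, "sampling rate must be positive")
  abort_if(length(source_power) != length(wavelengths),
           "one source power per wavelength required")
  abort_if(any(source_power <= 0) || any(detector_gain <= 0),
           "powers and gains must be positive")
  structure(list(wavelengths = as.numeric(wavelengths),
                 separations = as.numeric(separations), fs = fs,
                 source_power = source_power,
                 detector_gain = rep_len(detector_gain, length(separations)),
                 dpf = dpf),
            class = "instrument_model")
}

#' Breath-hold hemodynamic scenario
#'
#' Canonical cerebral response to voluntary apnea: an initial dip reaching
#' its minimum ~10 s after onset, a supra-baseline overshoot peaking at
#' 25-30 s, then relaxation toward baseline. Amplitudes are specified
#' separately for the HbO-concentration channel (uM) and the StO2 channel
#' (%); the defaults are calibrated to published group means of a 56-trial
#' breath-hold study: HbO dip -0.002 / peak +0.021 uM, and StO2 peak
#' +1.22 % ("ssds_scale" preset) or +0.48 % ("srs_scale" preset), with the
#' matching dips -0.04 % and -0.10 %.
#'
#' @param t_onset task onset time from recording start, s
#' @param hold_s breath-hold duration, s (study mean 41.4)
#' @param dip_time,peak_time extremum times after onset, s
#' @param recovery_tau time after the peak for the response to decay to 1/e
#'   of the peak, s (default 18, which leaves ~48 % of the peak at 40-45 s)
#' @param dip_tau decay constant of the dip kernel, s
#' @param hbo_dip,hbo_peak HbO change at dip/peak, uM
#' @param sto2_dip,sto2_peak StO2 change at dip/peak, %
#' @param preset `"ssds_scale"` (default) or `"srs_scale"`; sets the StO2
#'   amplitudes unless given explicitly
#' @export
breath_hold_scenario <- function(t_onset = 30, hold_s = 41.4,
                                 dip_time = 10, peak_time = 27.5,
                                 recovery_tau = 18, dip_tau = 5,
                                 hbo_dip = -0.002, hbo_peak = 0.021,
                                 sto2_dip = NULL, sto2_peak = NULL,
                                 preset = c("ssds_scale", "srs_scale")) {
  preset <- match.arg(preset)
  if (is.null(sto2_dip)) sto2_dip <- if (preset == "ssds_scale") -0.04 else -0.10
  if (is.null(sto2_peak)) sto2_peak <- if (preset == "ssds_scale") 1.22 else 0.48
  abort_if(dip_time >= peak_time, "dip must precede the peak")
  abort_if(t_onset < 5, "need at least 5 s of baseline before onset")
  abort_if(hold_s <= 0 || recovery_tau <= 0 || dip_tau <= 0,
           "durations and time constants must be positive")
  structure(list(t_onset = t_onset, hold_s = hold_s, dip_time = dip_time,
                 peak_time = peak_time, recovery_tau = recovery_tau,
                 dip_tau = dip_tau, hbo_dip = hbo_dip, hbo_peak = hbo_peak,
                 sto2_dip = sto2_dip, sto2_peak = sto2_peak, preset = preset),
            class = "breath_hold_scenario")
}

# Gamma-variate kernel normalised to peak 1 at t = tp, and its t-derivative.
gamma_kernel <- function(t, tp, a) ifelse(t <= 0, 0, ((t / tp) * exp(1 - t / tp))^a)
gamma_kernel_dt <- function(t, tp, a)
  ifelse(t <= 0, 0, gamma_kernel(t, tp, a) * a * (1 / t - 1 / tp))

# Shape parameter such that the kernel decays to 1/e of its peak a time
# `tau` after the peak.
shape_from_tau <- function(tp, tau) {
  x <- tau / tp
  -1 / log((1 + x) * exp(-x))
}

# Coefficients (tp1, tp2, A, B) of the double-gamma response such that the
# curve passes through the dip and peak with zero derivative at both, so its
# extrema sit exactly at the requested times. Damped Newton on 4 equations;
# kernel peak times are solved in log space to stay positive.
solve_bh_kernels <- function(dip_time, dip_amp, peak_time, peak_amp, a1, a2) {
  Ffun <- function(x) {
    tp1 <- exp(x[1]); tp2 <- exp(x[2]); A <- x[3]; B <- x[4]
    c(A * gamma_kernel(dip_time, tp1, a1) + B * gamma_kernel(dip_time, tp2, a2) - dip_amp,
      A * gamma_kernel_dt(dip_time, tp1, a1) + B * gamma_kernel_dt(dip_time, tp2, a2),
      A * gamma_kernel(peak_time, tp1, a1) + B * gamma_kernel(peak_time, tp2, a2) - peak_amp,
      A * gamma_kernel_dt(peak_time, tp1, a1) + B * gamma_kernel_dt(peak_time, tp2, a2))
  }
  x <- c(log(dip_time), log(peak_time), dip_amp, peak_amp)
  Fv <- Ffun(x); fn <- sum(Fv^2)
  for (it in 1:200) {
    if (max(abs(Fv)) < 1e-13) break
    J <- matrix(0, 4, 4)
    h <- 1e-7
    for (j in 1:4) { xp <- x; xp[j] <- xp[j] + h; J[, j] <- (Ffun(xp) - Fv) / h }
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    abort_if(is.null(step), "breath-hold kernel solve failed (singular Jacobian)")
    lam <- 1
    repeat {
      Fn <- Ffun(x - lam * step)
      if (all(is.finite(Fn)) && sum(Fn^2) < fn) break
      lam <- lam / 2
      abort_if(lam < 1e-10, "breath-hold kernel solve failed to converge")
    }
    x <- x - lam * step; Fv <- Ffun(x); fn <- sum(Fv^2)
  }
  abort_if(max(abs(Fv)) > 1e-8, "breath-hold kernel solve did not converge")
  list(tp1 = exp(x[1]), tp2 = exp(x[2]), A = x[3], B = x[4])
}

#' Breath-hold response curve
#'
#' Smooth double-gamma-variate curve, zero before onset, constrained so that
#' its minimum equals `dip_amp` exactly at `dip_time` and its maximum equals
#' `peak_amp` exactly at `peak_time` (both relative to onset). Either
#' amplitude may be zero (dropping that kernel); both zero gives the flat
#' baseline.
#'
#' @param t_rel time since task onset, s (vector; values <= 0 give 0)
#' @param dip_time,dip_amp,peak_time,peak_amp extremum constraints
#' @param recovery_tau,dip_tau decay constants of the kernels, s
#' @return numeric vector of the response
#' @export
bh_response <- function(t_rel, dip_time, dip_amp, peak_time, peak_amp,
                        recovery_tau = 18, dip_tau = 5) {
  if (dip_amp == 0 && peak_amp == 0) return(rep(0, length(t_rel)))
  a1 <- shape_from_tau(dip_time, dip_tau)
  a2 <- shape_from_tau(peak_time, recovery_tau)
  if (dip_amp == 0) return(peak_amp * gamma_kernel(t_rel, peak_time, a2))
  if (peak_amp == 0) return(dip_amp * gamma_kernel(t_rel, dip_time, a1))
  k <- solve_bh_kernels(dip_time, dip_amp, peak_time, peak_amp, a1, a2)
  k$A * gamma_kernel(t_rel, k$tp1, a1) + k$B * gamma_kernel(t_rel, k$tp2, a2)
}

#' Ground-truth chromophore time series for a breath-hold scenario
#'
#' The HbO concentration follows the scenario's HbO-scale response; the true
#' StO2 follows its StO2-scale response; Hb is then fixed by
#' THb(t) = 100 * HbO(t) / StO2(t). Both curves share the extremum times, so
#' the generated state has its argmin/argmax at the scenario's dip/peak.
#'
#' @param scenario a [breath_hold_scenario()]
#' @param tissue a [tissue_model()]
#' @param t time grid (s, from recording start) covering onset - 5 s onward
#' @return tibble `time_s` plus the [chromophore_state()] columns
#' @export
breath_hold_concentrations <- function(scenario, tissue, t) {
  abort_if(min(t) > scenario$t_onset - 5,
           "time grid must start at least 5 s before onset")
  u <- t - scenario$t_onset
  h_hbo <- bh_response(u, scenario$dip_time, scenario$hbo_dip,
                       scenario$peak_time, scenario$hbo_peak,
                       scenario$recovery_tau, scenario$dip_tau)
  h_sto2 <- bh_response(u, scenario$dip_time, scenario$sto2_dip,
                        scenario$peak_time, scenario$sto2_peak,
                        scenario$recovery_tau, scenario$dip_tau)
  c_hbo0 <- tissue$sto2 / 100 * tissue$thb
  c_hbo <- c_hbo0 + h_hbo
  sto2 <- tissue$sto2 + h_sto2
  thb <- 100 * c_hbo / sto2
  st <- chromophore_state(c_hbo, thb - c_hbo)
  tibble::add_column(st, time_s = t, .before = 1)
}

#' Instrument noise model
#'
#' Multiplicative disturbances applied to the clean channel intensities:
#' per-sample white noise, systemic physiological oscillations (cardiac,
#' respiratory, Mayer waves; shared across all channels with random phase),
#' per-channel linear drift, and spike artifacts on the far (4 cm) detector
#' shared in time across its three wavelength channels but with
#' per-wavelength magnitude (a wavelength-uniform spike would cancel in
#' ratio-based estimators and never be seen). Amplitudes are relative
#' intensity units. The defaults describe a recording that survives the SNR
#' screen: 5-s-window noise roughly an order of magnitude below the
#' canonical response peak (see the methods vignette for the calibration
#' argument and for a discussion of the study's much larger group SEs).
#'
#' @param white_sd per-sample relative white-noise sd
#' @param cardiac_amp,cardiac_freq cardiac oscillation (default 1.1 Hz)
#' @param resp_amp,resp_freq respiratory oscillation (default 0.25 Hz)
#' @param mayer_amp,mayer_freq Mayer wave (default 0.1 Hz)
#' @param drift_sd_per_s sd of the per-channel relative drift slope, 1/s
#' @param spike_rate Poisson rate of spike events on the far detector, 1/s
#' @param spike_amp relative spike magnitude scale
#' @param spike_times explicit event times (s), overriding the Poisson draw
#' @param longhold_amp,longhold_freq extra low-frequency fluctuation during
#'   holds longer than `longhold_threshold` s
#' @param longhold_threshold hold duration (s) above which the long-hold
#'   fluctuation is enabled
#' @param seed RNG seed for the recording (overridden by the `seed` argument
#'   of [simulate_recording()])
#' @export
noise_model <- function(white_sd = 5e-4,
                        cardiac_amp = 2e-4, cardiac_freq = 1.1,
                        resp_amp = 1e-4, resp_freq = 0.25,
                        mayer_amp = 1e-4, mayer_freq = 0.1,
                        drift_sd_per_s = 1e-5,
                        spike_rate = 0.01, spike_amp = 0.05,
                        spike_times = NULL,
                        longhold_amp = 5e-4, longhold_freq = 0.05,
                        longhold_threshold = 60, seed = NULL) {
  amps <- c(white_sd, cardiac_amp, resp_amp, mayer_amp, drift_sd_per_s,
            spike_rate, spike_amp, longhold_amp)
  abort_if(any(amps < 0), "noise amplitudes must be >= 0")
  structure(list(white_sd = white_sd, cardiac_amp = cardiac_amp,
                 cardiac_freq = cardiac_freq, resp_amp = resp_amp,
                 resp_freq = resp_freq, mayer_amp = mayer_amp,
                 mayer_freq = mayer_freq, drift_sd_per_s = drift_sd_per_s,
                 spike_rate = spike_rate, spike_amp = spike_amp,
                 spike_times = spike_times, longhold_amp = longhold_amp,
                 longhold_freq = longhold_freq,
                 longhold_threshold = longhold_threshold, seed = seed),
            class = "noise_model")
}

#' Silent noise model (all amplitudes zero)
#' @export
no_noise <- function() noise_model(white_sd = 0, cardiac_amp = 0, resp_amp = 0,
                                   mayer_amp = 0, drift_sd_per_s = 0,
                                   spike_rate = 0, spike_amp = 0,
                                   longhold_amp = 0)

#' Simulate one breath-hold CW-NIRS recording
#'
#' Forward-models each sample: chromophore concentrations from the scenario,
#' mu_a per wavelength, channel intensity per (wavelength, separation), then
#' noise, drift, and spikes. Two generator modes:
#' * `"mbll_exact"`: I = P 10^(-DPF d mu_a - G) — the single-exponential
#'   model under which the SSDS estimator is provably exact (algorithm
#'   verification mode);
#' * `"diffusion"`: intensities from [diffusion_reflectance()] — physically
#'   realistic; estimator tolerances on this mode are empirical.
#'
#' @param tissue a [tissue_model()]
#' @param scenario a [breath_hold_scenario()]
#' @param noise a [noise_model()]
#' @param instrument an [instrument_model()]
#' @param mode generator mode (see above); default `"diffusion"`
#' @param duration_s recording length; default onset + 60 s
#' @param seed RNG seed (takes precedence over `noise$seed`); identical
#'   seed and parameters give a bit-identical recording
#' @return object of class `nirs_simulation`: list with `recording` (a
#'   [nirs_recording()]) and `truth` (ground-truth concentrations and all
#'   generating parameters, sufficient to recompute every intermediate)
#' @export
simulate_recording <- function(tissue = tissue_model(),
                               scenario = breath_hold_scenario(),
                               noise = noise_model(),
                               instrument = instrument_model(),
                               mode = c("diffusion", "mbll_exact"),
                               duration_s = NULL, seed = NULL) {
  mode <- match.arg(mode)
  seed <- seed %||% noise$seed
  duration_s <- duration_s %||% (scenario$t_onset + 60)
  fs <- instrument$fs
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  conc <- breath_hold_concentrations(scenario, tissue, t)
  mua <- absorption_from_state(conc, extinction_table(), instrument$wavelengths)
  wl <- instrument$wavelengths
  seps <- instrument$separations
  coupling <- rep_len(tissue$coupling_od, length(seps))
  clean <- matrix(NA_real_, length(t), length(wl) * length(seps))
  cn <- character(ncol(clean))
  k <- 0
  for (si in seq_along(seps)) {
    for (wi in seq_along(wl)) {
      k <- k + 1
      cn[k] <- channel_name(wl[wi], seps[si])
      shape <- if (mode == "mbll_exact") {
        10^(-instrument$dpf * seps[si] * mua[, wi])
      } else {
        diffusion_reflectance(mua[, wi], tissue$musp[wi], seps[si], tissue$n_ref)
      }
      clean[, k] <- instrument$source_power[wi] * instrument$detector_gain[si] *
        10^(-coupling[si]) * shape
    }
  }
  colnames(clean) <- cn

  sim_once <- function() {
    I <- clean
    # systemic oscillations, shared across channels
    osc <- rep(0, length(t))
    for (comp in list(c(noise$cardiac_amp, noise$cardiac_freq),
                      c(noise$resp_amp, noise$resp_freq),
                      c(noise$mayer_amp, noise$mayer_freq))) {
      if (comp[1] > 0)
        osc <- osc + comp[1] * sin(2 * pi * comp[2] * t + runif(1, 0, 2 * pi))
    }
    if (noise$longhold_amp > 0 && scenario$hold_s > noise$longhold_threshold) {
      inhold <- t >= scenario$t_onset & t <= scenario$t_onset + scenario$hold_s
      osc[inhold] <- osc[inhold] + noise$longhold_amp *
        sin(2 * pi * noise$longhold_freq * t[inhold] + runif(1, 0, 2 * pi))
    }
    I <- I * (1 + osc)
    for (j in seq_len(ncol(I))) {
      if (noise$drift_sd_per_s > 0)
        I[, j] <- I[, j] * (1 + rnorm(1, 0, noise$drift_sd_per_s) * t)
      if (noise$white_sd > 0)
        I[, j] <- I[, j] * (1 + rnorm(length(t), 0, noise$white_sd))
    }
    # spike artifacts: far detector only, event times shared across its
    # wavelengths, per-wavelength magnitude
    spike_t <- noise$spike_times
    if (is.null(spike_t) && noise$spike_rate > 0) {
      n_ev <- stats::rpois(1, noise$spike_rate * duration_s)
      spike_t <- sort(runif(n_ev, 0, duration_s))
    }
    if (is.null(spike_t)) spike_t <- numeric(0)
    spike_t <- spike_t[spike_t >= 0 & spike_t < duration_s]
    if (length(spike_t) > 0 && noise$spike_amp > 0 && length(seps) > 1) {
      far_cols <- channel_name(wl, seps[length(seps)])
      # alternating sign pattern across wavelengths: a spike that moved all
      # three channels by the same factor would cancel in the ratio-based
      # estimators and never be observable
      pattern <- c(1, -1, 1)
      for (ts in spike_t) {
        idx <- which.min(abs(t - ts))
        sgn <- sample(c(-1, 1), 1)
        for (j in seq_along(far_cols)) {
          I[idx, far_cols[j]] <- I[idx, far_cols[j]] *
            (1 + sgn * pattern[j] * noise$spike_amp * runif(1, 0.5, 1.5))
        }
      }
    }
    list(I = I, spike_t = spike_t)
  }
  res <- if (is.null(seed)) sim_once() else with_seed(seed, sim_once())

  rec <- nirs_recording(
    data = tibble::as_tibble(cbind(tibble::tibble(time_s = t),
                                   tibble::as_tibble(res$I))),
    wavelengths = wl, separations = seps, fs = fs,
    meta = list(mode = mode, seed = seed)
  )
  truth <- list(
    concentrations = conc,
    mu_a = mua,
    clean_intensity = tibble::as_tibble(clean),
    k = c(k1 = instrument$source_power[1] / instrument$source_power[2],
          k2 = instrument$source_power[3] / instrument$source_power[2]),
    spike_times = res$spike_t,
    tissue = tissue, scenario = scenario, noise = noise,
    instrument = instrument, mode = mode, seed = seed
  )
  structure(list(recording = rec, truth = truth), class = "nirs_simulation")
}

# Truncated-lognormal hold duration. meanlog/sdlog solved (moment matching
# on the truncated distribution) so that after truncation to [17.5, 120] s
# the mean and sd are the study's 41.4 and 22.4 s.
HOLD_MEANLOG <- 3.1294638093
HOLD_SDLOG <- 0.8822483142

#' Sample breath-hold durations
#'
#' Lognormal, rejection-truncated to the study's observed range
#' [17.5, 120] s, calibrated so the truncated mean/sd are 41.4/22.4 s.
#'
#' @param n number of draws
#' @param spread scale factor on the lognormal sdlog; 0 returns the constant
#'   mean duration 41.4 s
#' @return numeric vector of durations, s
#' @export
sample_hold_durations <- function(n, spread = 1) {
  if (spread == 0) return(rep(41.4, n))
  out <- numeric(0)
  while (length(out) < n) {
    d <- rlnorm(2 * n + 20, HOLD_MEANLOG, HOLD_SDLOG * spread)
    out <- c(out, d[d >= 17.5 & d <= 120])
  }
  out[seq_len(n)]
}

#' Between-subject variability of the synthetic group
#'
#' @param amplitude_cv lognormal coefficient of variation of a per-subject
#'   scale applied to all response amplitudes
#' @param sto2_sd,thb_sd,musp_sd sd of the per-subject baseline StO2 (%),
#'   THb (uM) and mu_s' (cm^-1)
#' @param hold_spread scale on the hold-duration lognormal spread (0 =
#'   constant 41.4 s)
#' @export
group_variability <- function(amplitude_cv = 0.3, sto2_sd = 3, thb_sd = 6,
                              musp_sd = 1, hold_spread = 1) {
  structure(list(amplitude_cv = amplitude_cv, sto2_sd = sto2_sd,
                 thb_sd = thb_sd, musp_sd = musp_sd,
                 hold_spread = hold_spread),
            class = "group_variability")
}

#' Simulate a group breath-hold dataset
#'
#' Draws per-subject baseline optical properties and response-amplitude
#' scales, per-trial hold durations, and simulates every recording. The
#' default design mirrors the study's retained cohort: 19 subjects, 18 of
#' them with 3 trials and one with 2, i.e. 56 recordings.
#'
#' @param n_subjects number of subjects
#' @param trials_per_subject scalar or per-subject vector; default
#'   `c(rep(3, 18), 2)` when `n_subjects` is 19
#' @param variability a [group_variability()]
#' @param tissue,scenario,noise,instrument,mode templates passed to
#'   [simulate_recording()]
#' @param seed master seed; per-recording seeds are derived from it, so the
#'   whole dataset is reproducible
#' @return object of class `nirs_group`: list with `recordings` (list of
#'   `nirs_simulation`) and `manifest` (tibble subject_id, trial_id,
#'   onset_s, hold_s, seed)
#' @export
simulate_group <- function(n_subjects = 19, trials_per_subject = NULL,
                           variability = group_variability(),
                           tissue = tissue_model(),
                           scenario = breath_hold_scenario(),
                           noise = noise_model(),
                           instrument = instrument_model(),
                           mode = c("diffusion", "mbll_exact"), seed = NULL) {
  mode <- match.arg(mode)
  abort_if(n_subjects < 1, "need at least one subject")
  if (is.null(trials_per_subject))
    trials_per_subject <- if (n_subjects == 19) c(rep(3, 18), 2) else 3
  trials <- rep_len(trials_per_subject, n_subjects)
  run <- function() {
    recs <- list()
    man <- list()
    idx <- 0
    for (s in seq_len(n_subjects)) {
      v <- variability
      amp <- if (v$amplitude_cv > 0) {
        sdl <- sqrt(log(1 + v$amplitude_cv^2))
        rlnorm(1, -sdl^2 / 2, sdl)  # mean-1 lognormal scale
      } else 1
      ts <- tissue_model(
        sto2 = min(90, max(40, tissue$sto2 + rnorm(1, 0, v$sto2_sd))),
        thb = max(20, tissue$thb + rnorm(1, 0, v$thb_sd)),
        musp = pmax(5, tissue$musp + rnorm(1, 0, v$musp_sd)),
        n_ref = tissue$n_ref, coupling_od = tissue$coupling_od)
      for (tr in seq_len(trials[s])) {
        idx <- idx + 1
        hold <- sample_hold_durations(1, v$hold_spread)
        sc <- scenario
        sc$hold_s <- hold
        sc$hbo_dip <- scenario$hbo_dip * amp
        sc$hbo_peak <- scenario$hbo_peak * amp
        sc$sto2_dip <- scenario$sto2_dip * amp
        sc$sto2_peak <- scenario$sto2_peak * amp
        rec_seed <- sample.int(.Machine$integer.max, 1)
        recs[[idx]] <- simulate_recording(ts, sc, noise, instrument,
                                          mode = mode, seed = rec_seed)
        man[[idx]] <- tibble::tibble(subject_id = s, trial_id = tr,
                                     onset_s = sc$t_onset, hold_s = hold,
                                     seed = rec_seed)
      }
    }
    list(recordings = recs, manifest = do.call(rbind, man))
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(c(out, list(seed = seed, mode = mode)), class = "nirs_group")
}
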