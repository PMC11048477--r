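# Shared fixtures, all built in code.

default_tab <- extinction_table()

# Intensities under the single-exponential forward model
# I(lambda) = P(lambda) * 10^(-dpf * d * mu_a(lambda) - G)
exact_intensities <- function(sto2, thb, G = 0, d = 3, dpf = 6,
                              P = c(1, 0.9, 1.1), tab = default_tab) {
  st <- chromophore_state(sto2 / 100 * thb, (1 - sto2 / 100) * thb)
  mua <- as.numeric(absorption_from_state(st, tab))
  P * 10^(-dpf * d * mua - G)
}

cal_from_powers <- function(P = c(1, 0.9, 1.1)) {
  ssds_calibration(P[1] / P[2], P[3] / P[2])
}

# A short constant-tissue recording (flat scenario), noiseless by default
flat_sim <- function(mode = "mbll_exact", duration_s = 20, fs = 120,
                     noise = no_noise(), ...) {
  sc <- breath_hold_scenario(t_onset = 8, hbo_dip = 0, hbo_peak = 0,
                             sto2_dip = 0, sto2_peak = 0)
  simulate_recording(scenario = sc, noise = noise,
                     instrument = instrument_model(fs = fs),
                     mode = mode, duration_s = duration_s, ...)
}

# Independent reference statistics, written from the classical closed forms
# (the package's own routines are not reused here).
ref_anova <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  m_i <- vapply(groups, mean, 1.0)
  gm <- sum(unlist(groups)) / N
  ssb <- sum(n * (m_i - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

ref_t <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(abs(t), n - 1, lower.tail = FALSE))
}

ref_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) * length(x) / (length(x) - 1)
}
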