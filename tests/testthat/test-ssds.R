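test_that("pairwise log terms vanish for unit ratios and mirror each other", {
  cal <- ssds_calibration(1, 1)
  A <- pairwise_attenuation_differences(2, 2, 2, cal)
  expect_equal(unlist(A), c(a12 = 0, a32 = 0, a31 = 0))
  # the denominator's third log term log(k1 i3/(k2 i1)) is the exact
  # negative of the numerator's a31 for any positive input
  set.seed(5)
  for (i in 1:10) {
    iv <- runif(3, 0.1, 10)
    cal <- ssds_calibration(runif(1, 0.5, 2), runif(1, 0.5, 2))
    A <- pairwise_attenuation_differences(iv[1], iv[2], iv[3], cal)
    neg31 <- log10(cal$k1 * iv[3] / (cal$k2 * iv[1]))
    expect_equal(A$a31 + neg31, 0, tolerance = 1e-14)
  }
  expect_error(pairwise_attenuation_differences(1, -1, 1, cal), "positive")
})

test_that("log terms equal the forward model's pairwise attenuation differences", {
  P <- c(1.3, 0.8, 1.05)
  dpf <- 6; d <- 3.5; G <- 0.7
  st <- chromophore_state(45, 20)
  mua <- as.numeric(absorption_from_state(st, default_tab))
  I <- P * 10^(-dpf * d * mua - G)
  A <- pairwise_attenuation_differences(I[1], I[2], I[3], cal_from_powers(P))
  L <- dpf * d
  expect_equal(A$a12, L * (mua[1] - mua[2]), tolerance = 1e-12)
  expect_equal(A$a32, L * (mua[3] - mua[2]), tolerance = 1e-12)
  expect_equal(A$a31, L * (mua[3] - mua[1]), tolerance = 1e-12)
})

test_that("SSDS recovers true saturation exactly under the homogeneous model", {
  cal <- cal_from_powers()
  for (S in c(10, 55, 90)) {
    for (G in c(0, 2.5)) {
      I <- exact_intensities(S, 60, G = G, d = 3)
      r <- ssds_sto2(I, cal, equal_dpf(6), default_tab)
      expect_equal(r$sto2, S, tolerance = 1e-9)
    }
  }
  # single-chromophore limit
  I <- exact_intensities(100, 40, G = 1, d = 4)
  expect_equal(ssds_sto2(I, cal, equal_dpf(6), default_tab)$sto2, 100,
               tolerance = 1e-9)
})

test_that("SSDS is invariant to a common intensity factor and covariant in k", {
  cal <- cal_from_powers()
  I <- exact_intensities(63, 70, G = 0.4)
  base <- ssds_sto2(I, cal, equal_dpf(), default_tab)$sto2
  for (g in c(1e-3, 0.2, 41)) {
    expect_equal(ssds_sto2(g * I, cal, equal_dpf(), default_tab)$sto2, base,
                 tolerance = 1e-9)
  }
  # scaling i1 by g while scaling k1 by g leaves the estimate unchanged
  g <- 3.7
  I2 <- I; I2[1] <- I2[1] * g
  cal2 <- ssds_calibration(cal$k1 * g, cal$k2)
  expect_equal(ssds_sto2(I2, cal2, equal_dpf(), default_tab)$sto2, base,
               tolerance = 1e-9)
})

test_that("estimated saturation is strictly increasing in true saturation", {
  cal <- cal_from_powers()
  grid <- seq(5, 95, by = 5)
  est <- vapply(grid, function(S)
    ssds_sto2(exact_intensities(S, 60), cal, equal_dpf(), default_tab)$sto2, 1.0)
  expect_true(all(diff(est) > 0))
})

test_that("the estimate does not depend on the logarithm base", {
  cal <- cal_from_powers()
  I <- exact_intensities(72, 55, G = 1)
  eps <- cbind(default_tab$eps_hbo, default_tab$eps_hb)
  s_for_base <- function(b) {
    A <- pairwise_attenuation_differences(I[1], I[2], I[3], cal, base = b)
    hb <- eps[, 2]; dd <- eps[, 1] - eps[, 2]
    num <- A$a12 * hb[3] - A$a32 * hb[1] + A$a31 * hb[2]
    den <- A$a32 * dd[1] - A$a12 * dd[3] - A$a31 * dd[2]
    100 * num / den
  }
  expect_equal(s_for_base(10), s_for_base(exp(1)), tolerance = 1e-12)
})

test_that("a vanishing denominator is flagged, never a fabricated value", {
  r <- ssds_sto2(c(1, 1, 1), ssds_calibration(1, 1), equal_dpf(), default_tab)
  expect_true(r$flag_denominator_near_zero)
  expect_true(is.na(r$sto2))
})

test_that("out-of-range values are reported unclamped with a flag", {
  # diffusion-model intensities at high saturation push the equal-DPF
  # estimate above 100 % (model mismatch), which must surface as a flag
  P <- c(1, 0.9, 1.1)
  st <- chromophore_state(0.9 * 60, 0.1 * 60)
  mua <- as.numeric(absorption_from_state(st, default_tab))
  I <- P * diffusion_reflectance(mua, 10, 3)
  r <- ssds_sto2(I, cal_from_powers(P), equal_dpf(), default_tab)
  expect_false(is.na(r$sto2))
  expect_gt(r$sto2, 100)
  expect_true(r$flag_out_of_physio_range)
})

test_that("constant synthetic tissue yields a constant trace at truth", {
  sim <- flat_sim()
  cal <- ssds_calibration(sim$truth$k[["k1"]], sim$truth$k[["k2"]])
  tr <- ssds_timeseries(sim$recording, 3, cal)
  expect_lt(max(abs(tr$sto2 - 70)), 1e-9)
  expect_lt(diff(range(tr$sto2)), 1e-9)
})

test_that("trace extrema track the scenario's dip and peak on noiseless data", {
  sim <- simulate_recording(noise = no_noise(), mode = "mbll_exact", seed = 2)
  cal <- ssds_calibration(sim$truth$k[["k1"]], sim$truth$k[["k2"]])
  tr <- ssds_timeseries(sim$recording, 3, cal)
  truth <- sim$truth$concentrations
  fs <- sim$recording$fs
  expect_lte(abs(which.min(tr$sto2) - which.min(truth$sto2)), 1)
  expect_lte(abs(which.max(tr$sto2) - which.max(truth$sto2)), 1)
  expect_equal(tr$time_s[which.min(tr$sto2)], 30 + 10, tolerance = 1.5 / fs)
  expect_equal(tr$time_s[which.max(tr$sto2)], 30 + 27.5, tolerance = 1.5 / fs)
})

test_that("a zero-intensity sample is flagged locally without spreading", {
  sim <- flat_sim()
  rec <- sim$recording
  rec$data$i_800nm_3cm[500] <- 0
  cal <- ssds_calibration(sim$truth$k[["k1"]], sim$truth$k[["k2"]])
  tr <- ssds_timeseries(rec, 3, cal)
  expect_true(tr$flag_nonpositive_intensity[500])
  expect_true(is.na(tr$sto2[500]))
  expect_false(anyNA(tr$sto2[c(499, 501)]))
  expect_error(ssds_timeseries(rec, 7, cal), "i_730nm_7cm")
})

test_that("k calibration recovers the generating source ratios", {
  expect_equal(unclass(calibrate_k(NULL, "source_spec", source_ratios = c(1, 1))),
               list(k1 = 1, k2 = 1), ignore_attr = TRUE)
  sim <- flat_sim()
  cal <- calibrate_k(sim$recording, "baseline_assumed_sto2", separation = 3,
                     baseline_epoch = c(0, 5), assumed_sto2 = 70,
                     assumed_thb = 60, dpf = equal_dpf(6))
  expect_equal(cal$k1, sim$truth$k[["k1"]], tolerance = 1e-6)
  expect_equal(cal$k2, sim$truth$k[["k2"]], tolerance = 1e-6)
  expect_error(calibrate_k(sim$recording, "baseline_assumed_sto2",
                           separation = 3, baseline_epoch = c(0, 0.5)),
               "shorter")
})

test_that("a wrong assumed baseline saturation gives a monotone offset", {
  sim <- flat_sim()
  est <- vapply(c(60, 65, 70, 75, 80), function(s0) {
    cal <- calibrate_k(sim$recording, "baseline_assumed_sto2", separation = 3,
                       baseline_epoch = c(0, 5), assumed_sto2 = s0,
                       assumed_thb = 60, dpf = equal_dpf(6))
    mean(ssds_timeseries(sim$recording, 3, cal)$sto2)
  }, 1.0)
  expect_true(all(diff(est) > 0))
  expect_equal(est[3], 70, tolerance = 1e-6)  # correct assumption, no offset
})
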