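test_that("window means follow the midpoint rule on dense grids", {
  fs <- 120
  t <- seq(-10, 50, by = 1 / fs)
  w <- epoch_windows(t, rep(3.7, length(t)), onset = 0)
  expect_equal(nrow(w), 10)
  expect_true(all(w$mean == 3.7))
  # a pure time ramp averages to the window midpoints (up to half a sample)
  w <- epoch_windows(t, t, onset = 0)
  expect_equal(w$mean, seq(-2.5, 42.5, by = 5), tolerance = 1 / fs)
  expect_equal(w$window_start, seq(-5, 40, by = 5))
})

test_that("QC-flagged samples are excluded and coverage gaps are reported", {
  t <- seq(-5, 45, by = 0.1)
  v <- rep(1, length(t)); v[t >= 0 & t < 2.5] <- 100
  qc <- t >= 0 & t < 2.5
  w <- epoch_windows(t, v, onset = 0, qc = qc)
  expect_true(all(w$mean == 1))  # contaminated half-window fully excluded
  expect_lt(w$n[w$window_start == 0], w$n[w$window_start == 5])
  expect_error(epoch_windows(t, v, onset = 20), "cover")
})

test_that("baseline subtraction zeroes the baseline and is idempotent", {
  w <- epoch_windows(seq(-5, 44.99, by = 0.01), rnorm(5000), onset = 0)
  b <- baseline_subtract(w)
  expect_identical(b$mean[b$window_start == -5], 0)
  expect_identical(baseline_subtract(b), b)
  w2 <- w; w2$mean <- w2$mean + 17.3
  expect_equal(baseline_subtract(w2)$mean, b$mean, tolerance = 1e-12)
})

test_that("one-way ANOVA reproduces the hand-computed F on a tiny design", {
  # groups {1,2} and {3,4}: SSB = 4, SSW = 1 -> F = 8 with df (1, 2)
  r <- oneway_anova(list(c(1, 2), c(3, 4)))
  expect_equal(r$F, 8)
  expect_equal(c(r$df1, r$df2), c(1, 2))
  expect_equal(r$p, pf(8, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  # identical group means: no between-group variance
  r0 <- oneway_anova(list(c(1, 3), c(2, 2), c(3, 1)))
  expect_lt(r0$F, 1e-12)
  expect_error(oneway_anova(list(c(1, 1), c(1, 1))), "variance")
})

test_that("ANOVA agrees with an independent closed-form implementation", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3)))
    got <- oneway_anova(groups)
    ref <- ref_anova(groups)
    expect_equal(got$F, ref$F, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
    expect_equal(c(got$df1, got$df2), c(ref$df1, ref$df2))
  }
})

test_that("one-sample t matches the closed form and its df-2 CDF", {
  r <- one_sample_t(c(-1, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # closed-form Student CDF for df = 2: F(t) = 1/2 + t / (2 sqrt(2 + t^2))
  p_closed <- 2 * (1 - (0.5 + r$t / (2 * sqrt(2 + r$t^2))))
  expect_equal(r$p, p_closed, tolerance = 1e-12)
  expect_equal(one_sample_t(2 * c(1, 2, 3))$t, r$t, tolerance = 1e-12)
  expect_error(one_sample_t(c(2, 2, 2)), "variance")
})

test_that("t statistics agree with the independent closed form on random data", {
  set.seed(43)
  for (i in 1:100) {
    x <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    got <- one_sample_t(x)
    ref <- ref_t(x)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("Pearson correlation handles exact and hand-computed cases", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  set.seed(44)
  for (i in 1:50) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(pearson_r(x, y), ref_pearson(x, y), tolerance = 1e-10)
  }
})

test_that("the SNR screen separates clean from noise-dominated recordings", {
  clean <- flat_sim()
  expect_true(snr_screen(clean$recording, threshold = 1e12)$pass)
  # noise-dominated: fluctuation comparable to the mean level
  set.seed(10)
  t <- seq(0, 10, by = 1 / 120)
  mk <- function(sd_rel) {
    d <- tibble::tibble(time_s = t)
    for (wl in c(730, 800, 850)) for (sp in c(3, 4))
      d[[channel_name(wl, sp)]] <- pmax(1e-6, 1 + rnorm(length(t), 0, sd_rel))
    nirs_recording(d, c(730, 800, 850), c(3, 4), 120)
  }
  expect_false(snr_screen(mk(0.8), threshold = 100)$pass)
  # metric never increases with the noise level (fixed seed per level)
  metrics <- vapply(c(0.001, 0.01, 0.1, 0.5), function(sdr) {
    set.seed(77)
    min(snr_screen(mk(sdr))$metrics$snr)
  }, 1.0)
  expect_true(all(diff(metrics) < 0))
})

test_that("group analysis scales standard errors as 1/sqrt(n)", {
  set.seed(12)
  wt <- do.call(rbind, lapply(1:8, function(tr) {
    tibble::tibble(trial = tr, signal = "hbo_3cm",
                   window_start = seq(-5, 40, by = 5),
                   value = c(0, rnorm(9, mean = seq(0, 2, length.out = 9))))
  }))
  r1 <- group_analysis(wt)
  wt2 <- rbind(wt, within(wt, trial <- trial + 100))
  r2 <- group_analysis(wt2)
  expect_equal(r2$summary$mean, r1$summary$mean, tolerance = 1e-12)
  # duplicating n trials rescales the SE by sqrt((n-1)/(2n-1)) ~ 1/sqrt(2)
  expect_equal(r2$summary$se, r1$summary$se * sqrt(7 / 15), tolerance = 1e-10)
  expect_equal(r2$anova$df1, 9)
})

test_that("correlation matrices are symmetric with unit diagonal in both modes", {
  set.seed(13)
  wt <- do.call(rbind, lapply(1:6, function(tr) {
    base <- rnorm(10)
    rbind(tibble::tibble(trial = tr, signal = "a",
                         window_start = seq(-5, 40, by = 5), value = base),
          tibble::tibble(trial = tr, signal = "b",
                         window_start = seq(-5, 40, by = 5),
                         value = base + rnorm(10, 0, 0.3)))
  }))
  for (mode in c("group_mean", "pooled")) {
    r <- group_analysis(wt, cor_mode = mode)
    C <- r$correlations
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), c(1, 1))
    expect_true(all(C >= -1 & C <= 1))
    expect_true(all(r$anova$F >= 0))
    expect_true(all(r$ttests$p > 0 & r$ttests$p <= 1))
  }
})
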