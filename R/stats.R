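#' Window means of a trace around a task onset
#'
#' Averages a trace over consecutive half-open windows `[t0, t0 + window_s)`
#' relative to `onset`, spanning `range_s` (default -5 to 45 s, i.e. ten 5-s
#' windows). QC-flagged samples are excluded from the means.
#'
#' @param time_s,values the trace
#' @param onset task onset time, s
#' @param window_s window width, s
#' @param range_s `c(first, last)` window bounds relative to onset
#' @param qc optional logical vector; `TRUE` samples are excluded
#' @return tibble `window_start`, `window_end` (s relative to onset),
#'   `mean`, `n`
#' @export
epoch_windows <- function(time_s, values, onset, window_s = 5,
                          range_s = c(-5, 45), qc = NULL) {
  abort_if(length(time_s) != length(values), "time and values lengths differ")
  starts <- seq(range_s[1], range_s[2] - window_s, by = window_s)
  keep <- !is.na(values)
  if (!is.null(qc)) keep <- keep & !qc
  u <- time_s - onset
  out <- lapply(starts, function(s) {
    sel <- keep & u >= s & u < s + window_s
    abort_if(!any(u >= s & u < s + window_s),
             "trace does not cover window [%g, %g) s", s, s + window_s)
    abort_if(!any(sel), "window [%g, %g) s has no usable samples", s, s + window_s)
    tibble::tibble(window_start = s, window_end = s + window_s,
                   mean = mean(values[sel]), n = sum(sel))
  })
  do.call(rbind, out)
}

#' Subtract the baseline window
#'
#' Subtracts the mean of the baseline window (default the one starting at
#' -5 s) from every window, making the baseline window exactly zero.
#' Idempotent and invariant to constant offsets.
#'
#' @param windows output of [epoch_windows()]
#' @param baseline_start start time of the baseline window, s
#' @export
baseline_subtract <- function(windows, baseline_start = -5) {
  i <- which(abs(windows$window_start - baseline_start) < 1e-9)
  abort_if(length(i) != 1, "no baseline window starting at %g s", baseline_start)
  windows$mean <- windows$mean - windows$mean[i]
  windows
}

#' Single-factor one-way ANOVA
#'
#' Classical between/within mean-square ratio with the F upper-tail p-value
#' (equal-variance one-way ANOVA, as used for the window-wise breath-hold
#' comparison). Groups are treated as independent (no repeated-measures
#' correction) — the convention of the breath-hold pipeline.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups of
#'   >= 2 values each, with nonzero within-group variance)
#' @return list `F`, `df1`, `df2`, `p`
#' @export
oneway_anova <- function(groups) {
  abort_if(!is.list(groups) || length(groups) < 2, "need at least 2 groups")
  abort_if(any(vapply(groups, length, 1L) < 2), "each group needs >= 2 values")
  within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  abort_if(within == 0, "zero within-group variance")
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}

#' One-sample two-tailed t-test against a fixed mean
#'
#' @param values numeric vector, n >= 2, nonzero variance
#' @param mu null-hypothesis mean (default 0)
#' @return list `t`, `df`, `p`
#' @export
one_sample_t <- function(values, mu = 0) {
  abort_if(length(values) < 2, "need at least 2 values")
  abort_if(stats::var(values) == 0, "zero sample variance")
  tt <- stats::t.test(values, mu = mu, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Pearson correlation coefficient
#'
#' @param x,y equal-length numeric vectors (n >= 3, nonzero variance)
#' @export
pearson_r <- function(x, y) {
  abort_if(length(x) != length(y), "x and y lengths differ")
  abort_if(length(x) < 3, "need at least 3 paired values")
  abort_if(stats::var(x) == 0 || stats::var(y) == 0, "zero variance")
  stats::cor(x, y)
}

#' Signal-to-noise screen for a raw recording
#'
#' Per-channel metric: mean intensity divided by the standard deviation of
#' the high-frequency residual (estimated as `sd(diff(x)) / sqrt(2)`, which
#' ignores slow physiological structure). A recording fails when any
#' required channel falls below the threshold — a configurable stand-in for
#' the study's (undefined) exclusion rule that discarded 7 of 26 data sets.
#'
#' @param rec a [nirs_recording()]
#' @param threshold minimum acceptable per-channel SNR (default 100)
#' @return list `pass` (logical), `metrics` (tibble channel, snr)
#' @export
snr_screen <- function(rec, threshold = 100) {
  stopifnot(inherits(rec, "nirs_recording"))
  cols <- setdiff(names(rec$data), "time_s")
  abort_if(length(cols) == 0 || nrow(rec$data) < 3, "recording is empty")
  snr <- vapply(cols, function(cl) {
    x <- rec$data[[cl]]
    hf <- stats::sd(diff(x)) / sqrt(2)
    if (hf == 0) Inf else mean(x) / hf
  }, 1.0)
  list(pass = all(snr >= threshold),
       metrics = tibble::tibble(channel = cols, snr = unname(snr)))
}

#' Group-level breath-hold statistics
#'
#' Pools all trials (trial = observation), per the breath-hold convention:
#' for each signal, a one-way ANOVA across the ten 5-s windows, post hoc
#' one-sample t-tests against zero for the windows at and after task onset
#' (the baseline window is identically zero by construction), the group
#' mean +/- SE per window, and Pearson correlations among signals.
#'
#' @param window_table long tibble with columns `trial`, `signal`,
#'   `window_start`, `value` of baseline-subtracted window means
#' @param cor_mode `"group_mean"` correlates the per-signal group-mean
#'   window series (10 points); `"pooled"` correlates across all
#'   trial-window pairs. The pipeline's source convention is ambiguous, so
#'   both are exposed and labelled.
#' @param p_adjust multiplicity correction for the post hoc t-tests
#'   (default `"none"`, matching uncorrected reporting; any
#'   [stats::p.adjust()] method accepted)
#' @return object of class `bh_stat_report`: list `anova`, `ttests`,
#'   `summary` (mean/SE per window), `correlations`, `cor_mode`, `n_trials`
#' @export
group_analysis <- function(window_table, cor_mode = c("group_mean", "pooled"),
                           p_adjust = "none") {
  cor_mode <- match.arg(cor_mode)
  need <- c("trial", "signal", "window_start", "value")
  abort_if(!all(need %in% names(window_table)),
           "window table must have columns %s", paste(need, collapse = ", "))
  n_trials <- length(unique(window_table$trial))
  abort_if(n_trials < 2, "need at least 2 trials")
  signals <- unique(window_table$signal)

  anova_rows <- list(); t_rows <- list(); sum_rows <- list()
  for (sg in signals) {
    d <- window_table[window_table$signal == sg, ]
    wins <- sort(unique(d$window_start))
    groups <- lapply(wins, function(w) d$value[d$window_start == w])
    # baseline window is identically 0 after subtraction; drop it from the
    # ANOVA groups only if it is degenerate *and* keeping it would make the
    # test undefined -- it never is here because other windows vary, so keep.
    an <- oneway_anova(groups)
    anova_rows[[sg]] <- tibble::tibble(signal = sg, F = an$F, df1 = an$df1,
                                       df2 = an$df2, p = an$p)
    post <- wins[wins >= 0]
    tt <- lapply(post, function(w) {
      v <- d$value[d$window_start == w]
      r <- one_sample_t(v)
      tibble::tibble(signal = sg, window_start = w, t = r$t, df = r$df, p = r$p)
    })
    tt <- do.call(rbind, tt)
    tt$p_adj <- stats::p.adjust(tt$p, method = p_adjust)
    t_rows[[sg]] <- tt
    sm <- lapply(wins, function(w) {
      v <- d$value[d$window_start == w]
      tibble::tibble(signal = sg, window_start = w, mean = mean(v),
                     se = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
    sum_rows[[sg]] <- do.call(rbind, sm)
  }

  series <- if (cor_mode == "group_mean") {
    sapply(signals, function(sg) {
      s <- sum_rows[[sg]]
      s$mean[order(s$window_start)]
    })
  } else {
    d <- window_table
    d <- d[order(d$signal, d$trial, d$window_start), ]
    sapply(signals, function(sg) d$value[d$signal == sg])
  }
  cors <- stats::cor(series)

  structure(list(anova = do.call(rbind, anova_rows),
                 ttests = do.call(rbind, t_rows),
                 summary = do.call(rbind, sum_rows),
                 correlations = cors, cor_mode = cor_mode,
                 n_trials = n_trials),
            class = "bh_stat_report")
}

#' @export
print.bh_stat_report <- function(x, ...) {
  cat(sprintf("Breath-hold group analysis (%d trials pooled; windows as independent groups)\n",
              x$n_trials))
  cat("\nOne-way ANOVA across windows:\n")
  print(x$anova)
  cat(sprintf("\nCorrelations (%s mode):\n", x$cor_mode))
  print(round(x$correlations, 3))
  invisible(x)
}
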