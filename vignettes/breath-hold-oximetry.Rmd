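---
title: "Breath-hold cerebral oximetry with single-separation and spatially resolved CW-NIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold cerebral oximetry with single-separation and spatially resolved CW-NIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwnirs)
```

## The measurement model

A continuous-wave NIRS probe illuminates the forehead with an LED at
$\lambda_{1,2,3} = 730, 800, 850$ nm and detects backscattered light at two
source–detector separations (SDS), $\rho = 3$ and $4$ cm, at 120 Hz. In the
near-infrared window the tissue absorption relevant to oximetry is carried
by two chromophores,

$$\mu_a(\lambda) = \varepsilon_{HbO}(\lambda)\,C_{HbO} +
  \varepsilon_{Hb}(\lambda)\,C_{Hb},$$

with extinction coefficients in cm$^{-1}\mu M^{-1}$ under the **base-10
(decadic) convention** throughout this package. The packaged default table
(`inst/extdata/hemoglobin_extinction.csv`) comes from the standard compiled
hemoglobin spectra; at 730 nm deoxyhemoglobin dominates, at 850 nm
oxyhemoglobin dominates, and 800 nm sits near the isosbestic point. Any
estimator accepts a user-supplied table, since device firmware may adopt a
different tabulation or an ln-scaled convention; all formulas here are
either explicitly decadic or log-base invariant.

Tissue oxygen saturation is
$StO_2 = 100\, C_{HbO}/(C_{HbO} + C_{Hb})$ (%). Total hemoglobin
$THb = C_{HbO} + C_{Hb}$ holds exactly for every constructed state, and
$StO_2$ is invariant to a common scale on both concentrations — the
property that lets SRS work with absorption known only up to scale.

## The SSDS estimator and why it is exact

`ssds_sto2()` evaluates the single source–detector separation formula: with
pairwise attenuation differences

$$A_{12} = \log\frac{k_1 I_{\lambda_2}}{I_{\lambda_1}},\quad
  A_{32} = \log\frac{k_2 I_{\lambda_2}}{I_{\lambda_3}},\quad
  A_{31} = \log\frac{k_2 I_{\lambda_1}}{k_1 I_{\lambda_3}},$$

$$StO_2 = 100\cdot\frac{DPF_3 A_{12}\varepsilon^{Hb}_3 - DPF_1 A_{32}\varepsilon^{Hb}_1 + DPF_2 A_{31}\varepsilon^{Hb}_2}
 {DPF_1 A_{32}(\varepsilon^{HbO}_1-\varepsilon^{Hb}_1) - DPF_3 A_{12}(\varepsilon^{HbO}_3-\varepsilon^{Hb}_3) - DPF_2 A_{31}(\varepsilon^{HbO}_2-\varepsilon^{Hb}_2)}.$$

Two readings of the constants $k_1, k_2$ are possible *a priori*; this
package fixes $k_1 = I_0(\lambda_1)/I_0(\lambda_2)$ and
$k_2 = I_0(\lambda_3)/I_0(\lambda_2)$, the **emitted**-intensity ratios.
Under that reading, for the single-exponential forward model
$I(\lambda) = I_0(\lambda)\,10^{-DPF\,d\,\mu_a(\lambda) - G}$ with a
wavelength-shared coupling loss $G$, every source term, gain and $G$ cancels
and each log term reduces to $L(\mu_a^{(i)} - \mu_a^{(j)})$ with
$L = DPF \cdot d$. Substituting the two-chromophore $\mu_a$ and expanding,
both numerator and denominator factor through the same cross-product of
extinction coefficients

$$D = \varepsilon^{HbO}_1\varepsilon^{Hb}_3 - \varepsilon^{HbO}_2\varepsilon^{Hb}_3
    - \varepsilon^{HbO}_3\varepsilon^{Hb}_1 + \varepsilon^{HbO}_2\varepsilon^{Hb}_1
    + \varepsilon^{HbO}_3\varepsilon^{Hb}_2 - \varepsilon^{HbO}_1\varepsilon^{Hb}_2,$$

leaving numerator $=L\,D\,C_{HbO}$ and denominator $=L\,D\,(C_{HbO}+C_{Hb})$:
the formula returns the true $StO_2$ *exactly*, for any $G$, any $d$, any
$THb$, in any log base. This cancellation was verified symbolically before
the implementation and is asserted numerically over a grid
$StO_2 \in \{0,10,\dots,100\}\,\%$, $THb \in \{30,60,120\}\,\mu M$,
$G \in \{0,1,3\}$ OD, $d \in \{3,4\}$ cm at $10^{-6}$ percentage points.
The alternative reading of $k$ as *detected* baseline ratios would make the
formula $0/0$ at baseline and was rejected. Likewise the typeset grouping
of the third log terms is taken as $\log(k_2 I_{\lambda_1}/(k_1
I_{\lambda_3}))$ and its reciprocal — the only grouping under which the
identity holds (numerator and denominator third terms are exact negatives,
which `pairwise_attenuation_differences()` preserves and the tests check).

Practical consequences: the estimate is invariant to a common factor on all
three intensities, covariant under per-wavelength gain changes absorbed
into $k$, and strictly increasing in true saturation. A denominator within
`den_tol` (default $10^{-12}$ in log-OD × extinction units) of zero yields
`NA` plus a QC flag, never a fabricated number; out-of-range values are
reported unclamped with a flag, clamping being a presentation choice.

`calibrate_k()` supplies $k$ either from the declared source specification
or from a baseline epoch plus an assumed baseline state (StO$_2$, THb): the
single-exponential model is inverted on the epoch-mean intensities. If the
assumed saturation is wrong the estimate acquires a systematic monotone
offset — demonstrated, not hidden, by a sensitivity test.

## The SRS comparator

Spatially resolved spectroscopy uses the spatial derivative of attenuation.
In the semi-infinite diffusion asymptote, $\ln$-attenuation grows as
$\mu_{eff}\rho + 2\ln\rho$ with
$\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}\approx\sqrt{3\mu_a\mu_s'}$, so the
two-point slope minus $2/\bar\rho$ (at the mean separation,
$\bar\rho = 3.5$ cm for this probe) squares to an absorption estimate up to
the assumed $\mu_s'(\lambda)$:

$$\mu_a(\lambda) \propto \big(\mathrm{slope}(\lambda) - 2/\bar\rho\big)^2 \,/\,
  \big(3\mu_s'(\lambda)\big).$$

`srs_sto2()` then solves the two-chromophore system; a common scale error
in $\mu_s'$ cancels in the saturation. The device's proprietary SRS is not
published, so this textbook form (with $\mu_s'$ wavelength-independent at
10 cm$^{-1}$ by default) is the package's comparator. Samples whose slope
does not exceed $2/\bar\rho$ are flagged invalid, not interpolated. A
relative gain between the two photodiodes biases the slope by
$\ln(g)/(\rho_2-\rho_1)$; a `gain_ratio` calibration constant (default 1)
is exposed for it.

Measured with the diffusion forward model before the main build (and frozen
into the tests): on noiseless simulations at $THb = 60\,\mu M$,
$\mu_s' = 10$ cm$^{-1}$, $n = 1.4$, the SRS estimate is monotone in true
saturation with absolute errors of $-0.7$ to $-2.7$ percentage points over
50–80 %, inside the 3 pp acceptance band.

## MBLL concentration changes

`mbll_timeseries()` computes $\Delta A = -\log_{10}(I/I_{ref})$ per channel
with the reference intensity averaged over a configurable epoch (default:
the 5 s before task onset, matching the statistics' baseline convention;
the device's internal reference is unpublished), then solves the
three-wavelength system
$\Delta A(\lambda) = d\,DPF(\lambda)\,(\varepsilon_{HbO}\Delta C_{HbO} +
\varepsilon_{Hb}\Delta C_{Hb})$ by least squares — all channels enter
symmetrically rather than privileging a wavelength pair. Non-positive
samples are flagged and linearly interpolated only across gaps of at most
`max_gap_s` (default 0.5 s); longer gaps propagate missingness. The DPF
default is 6.0, a conventional adult-forehead value, with all three
wavelengths equal — the analysis assumption of the breath-hold protocol.

## The synthetic generator and its calibration

The generator exists because the human recordings behind the breath-hold
protocol are not publicly deposited: every pipeline stage is therefore
validated against simulated data with known ground truth.

**Forward models.** Two modes, deliberately separated:

* `mbll_exact` — $I = P(\lambda)\,g\,10^{-DPF\,d\,\mu_a - G}$. SSDS is
  provably exact here; this mode isolates algorithmic correctness from
  physics fidelity.
* `diffusion` — `diffusion_reflectance()`, the steady-state semi-infinite
  two-dipole solution with extrapolated boundary ($z_0 = 1/(\mu_a+\mu_s')$,
  $z_b = 2AD$ from the internal-reflection parameter of $n = 1.4$,
  $\mu_{eff} = \sqrt{3\mu_a(\mu_a+\mu_s')}$), cross-checked against an
  independent numerical implementation at spot values. On this mode the
  equal-DPF assumption is *wrong on purpose*: the measured SSDS bias at the
  canonical baseline (StO$_2$ 70 %, THb 60 µM) is about $+5.5$ pp at 3 cm,
  growing with saturation, and baseline-subtracted StO$_2$ *changes* are
  amplified $\approx 1.4\times$ while SRS attenuates them
  ($\approx 0.9\times$). That ordering — SSDS responding more strongly than
  SRS to the same underlying change — mirrors the sensitivity contrast
  reported for the wearable device, though the package makes no claim of
  quantitative fidelity to it.

**Response curve.** The breath-hold response is a difference of two
gamma-variate kernels. Rather than fixing kernel peak times and accepting
shifted extrema of the mixture, the four parameters (two kernel times, two
weights) are solved by damped Newton iteration so the curve attains its
minimum *exactly* at the dip time with the dip amplitude and its maximum
exactly at the peak time with the peak amplitude. Kernel shapes derive from
decay constants: `dip_tau` (default 5 s) and `recovery_tau` (default 18 s,
chosen so the curve at 40–45 s retains ~48 % of its peak, matching the
published group mean of 0.010 µM there against a 0.021 µM peak).

**Calibration to the published group means.** Canonical amplitudes: HbO dip
$-0.002$ µM at 10 s, peak $+0.021$ µM at 27.5 s; StO$_2$ dip $-0.04$ %,
peak $+1.22$ % (`ssds_scale` preset) or $-0.10/+0.48$ % (`srs_scale`).
These are *group means* of a human cohort and conflate inter-subject
variability; the generator uses them as single-trial truth — a documented
stand-in, not a fidelity claim. Because the generator has one true StO$_2$,
both estimators see the same underlying change; the two presets let a user
match whichever signal scale they are validating. HbO and StO$_2$ curves
are tied by $THb(t) = 100\,C_{HbO}(t)/StO_2(t)$, so the generated state is
exactly consistent with both amplitude specifications.

**Group design.** 19 subjects, 18 × 3 + 1 × 2 = 56 trials. Hold durations
are lognormal, rejection-truncated to the observed 17.5–120 s range, with
`meanlog`/`sdlog` solved by moment matching so the *truncated* mean and sd
are 41.4 and 22.4 s. Between-subject variability: baseline StO$_2$
(sd 3 %), THb (sd 6 µM), $\mu_s'$ (sd 1 cm$^{-1}$), and a mean-one
lognormal amplitude scale (CV 0.3). Holds longer than 60 s receive an extra
low-frequency StO$_2$ fluctuation, reflecting the reported instability of
long holds.

**Noise.** Multiplicative on intensities: white noise (relative sd
$5\times10^{-4}$ per sample), systemic cardiac/respiratory/Mayer
oscillations (1.1/0.25/0.1 Hz; shared across channels, so they cancel in
the ratio-based StO$_2$ estimators and load mainly on MBLL), per-channel
linear drift (slope sd $10^{-5}$/s), and spike artifacts on the far
detector: event times shared across its three wavelength channels with an
alternating-sign wavelength pattern and random magnitudes — a
wavelength-uniform spike would cancel identically in SSDS/SRS and be
unobservable, contradicting the artifact sharing these traces must exhibit.
The default noise level is calibrated so that per-trial 5-s-window noise
sits roughly an order of magnitude below the canonical response peak. This
represents a *retained* recording — the kind that survives the SNR screen
(the protocol discarded 7 of 26 data sets for low SNR) — and keeps
ground-truth recovery tests sharp. The much larger group SEs printed for
the human cohort are dominated by inter-subject response heterogeneity
(timing and shape differences) that this generator deliberately omits;
passing tests on these simulations therefore demonstrates correctness of
the pipeline, not expected effect sizes on real data.

## The statistical pipeline

Window means use half-open intervals $[t_0, t_0+5)$ (avoiding
double-counting boundary samples), ten windows from $-5$ to 45 s around
onset regardless of the individual hold duration (the protocol's convention
given a 41.4 s mean hold); QC-flagged samples are excluded from means.
Baseline subtraction zeroes the $-5$–0 s window exactly, is idempotent and
shift-invariant. The ANOVA is the classical equal-variance one-way test
with windows as independent groups — no repeated-measures correction, which
`group_analysis()` inherits as the protocol's own convention, with trials
(not subjects) as observations. Post hoc one-sample two-tailed t-tests run
on the windows at and after onset (the baseline window is identically zero,
hence degenerate); p-values are uncorrected by default with
`p_adjust` exposed. Correlations among signals are computed on the
group-mean window series by default, with a pooled per-trial alternative —
the protocol's own choice between these is ambiguous, so both are exposed
and labelled. The classical tests delegate to R's `stats` machinery
(`oneway.test(var.equal = TRUE)`, `t.test`, `cor`); the test suite verifies
them against independently written closed-form implementations to
$10^{-10}$.

The SNR screen (`snr_screen()`) is a stated stand-in for the protocol's
undefined exclusion rule: per-channel mean intensity over the
high-frequency residual sd (estimated via first differences), thresholded
at 100 by default.

## Numerical choices

* Two-chromophore solves use QR least squares; systems with condition
  number above $10^8$ raise a singular-system error rather than returning
  noise-amplified estimates.
* The Newton solve of the response kernels runs in log space for the kernel
  times (positivity), with step halving, to $10^{-13}$ residuals; failure to
  converge is an error, not a silent fallback.
* All randomness flows through explicit seeds; a recording, a group, and
  every derived statistic are bit-reproducible given (parameters, seed).
  Per-recording seeds are drawn from the master seed, so subsets match
  full runs.
* Worksheets are plain CSV with `#` metadata headers (sampling rate,
  geometry, seed, configuration hash); the ground-truth sidecar is JSON
  carrying every generating parameter, from which the simulation can be
  regenerated exactly.

Problem sizes in the shipped tests: the exactness grid (198 cells), 200–500
sample round trips, a four-point SRS recovery curve, and a full 56-trial
group study at 120 Hz — the latter runs in well under a minute on one core
and is the package's own choice of a desk-scale validation study.

## Known limitations

* Homogeneous, two-chromophore tissue: no water/lipid background, no
  layered scalp/skull/brain geometry, no partial-volume or partial
  pathlength correction. Because only hemoglobin absorbs here, baseline
  $\mu_a \approx 0.05$ cm$^{-1}$ and the diffusion-mode effective DPF
  (~12 at 3 cm) exceeds the conventional 6.0 used for inversion: MBLL
  amplitudes on diffusion-mode data are correspondingly rescaled. Timing
  and significance conclusions are unaffected; absolute amplitude fidelity
  on this mode is not claimed.
* The device's proprietary SRS and its internal smoothing are unknown; the
  comparator here is the textbook diffusion-asymptote form.
* Group means stand in for single-trial truth, and the default noise is a
  retained-recording calibration; neither reproduces the human cohort's
  between-subject spread.
* No motion-artifact correction or short-channel regression; spikes are
  flagged/visible by design, not removed.
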