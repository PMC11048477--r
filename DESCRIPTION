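Package: cwnirs
Title: Continuous-Wave NIRS Cerebral Oximetry with Single-Separation and
    Spatially Resolved StO2 Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Signal-processing and statistics toolkit for continuous-wave
    near-infrared spectroscopy (CW-NIRS) cerebral oximetry. Implements
    absolute tissue oxygen saturation (StO2) from a single source-detector
    pair via three-wavelength attenuation differences (the SSDS algorithm),
    the two-separation spatially resolved spectroscopy (SRS) comparator,
    modified Beer-Lambert law hemoglobin concentration changes, a
    ground-truthed synthetic breath-hold data generator built on the
    semi-infinite diffusion forward model, and the breath-hold statistical
    pipeline (5-s window averaging, baseline subtraction, one-way ANOVA,
    post hoc one-sample t-tests, Pearson correlations, SNR screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
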