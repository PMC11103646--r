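Package: choicedyn
Title: Behavioral Dynamics of Early Choice Learning in Two-Alternative Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for trial-level behavioral data from rodent
    two-alternative forced-choice (2AFC) experiments that separate value
    learning (single-offer trials) from choice learning (dual-offer trials).
    Provides a canonical trial table format with validation, a synthetic
    cohort generator, descriptive behavioral measures (screened median
    latencies, choice and error percentages, dual-vs-single offer effects,
    robust within-session slowing), ex-Gaussian decomposition of response
    latency distributions by maximum likelihood with a simulate-and-test fit
    validation, a generalized drift-diffusion model with luminance-contrast
    dependent drift (analytic first-passage series, Crank-Nicolson
    Fokker-Planck solver, bridge-corrected simulator, lapse-mixture
    likelihood, differential-evolution fitting), and resampling statistics
    (paired sign-flip permutation tests with BCa bootstrap intervals,
    repeated-measures ANOVA and correlation, rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
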