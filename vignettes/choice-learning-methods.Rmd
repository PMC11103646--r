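---
title: "Models and methods for early choice-learning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for early choice-learning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicedyn)
```

## The experiment this package analyzes

`choicedyn` analyzes trial-level data from a rodent two-alternative
forced-choice (2AFC) task in which stimulus values are trained first and
choices are introduced later. Rats initiate trials at a center port; a
visual stimulus of high (8 LEDs) or low (2 LEDs) luminance appears over a
side port, each luminance paired with a different sucrose concentration.
During *value learning* only single offers occur. During *choice learning*,
two-thirds of trials remain single-offer and one-third become dual-offer
trials where both stimuli appear and the rat is free to choose. The
response latency — time from center poke to side poke — is the central
measurement: slowing on dual-offer relative to single-offer trials
("deliberation") indicates a comparative decision process, and its change
across the first five choice sessions indexes how choosing is learned.

The analysis pipeline combines three layers:

1. **Descriptive measures** — screened median latencies, high-value choice
   percentage on dual offers, error percentage on single offers, the
   dual-minus-single *offer effect*, and robust within-session slowing.
2. **Ex-Gaussian decomposition** of latency distributions into a Gaussian
   component (`mu`, `sigma`; the sensorimotor peak) and an exponential tail
   (`tau`; decision variability).
3. **A generalized drift-diffusion model (DDM)** of dual-offer choices, with
   drift proportional to the log luminance contrast, fit per session and
   per rat by maximum likelihood.

Inference uses paired sign-flip permutation tests with BCa bootstrap
intervals, Bonferroni correction, repeated-measures ANOVA with subject
error terms, and repeated-measures correlation.

## Latency screening and medians

Latencies above 3 s are screened out as task disengagement before any
latency analysis; error trials (responses at the non-illuminated port on
single offers) are excluded from latency distributions and analyzed only as
rates. Medians use the linear-interpolation convention for even group
sizes, and cohort summaries average per-rat medians so the rat remains the
experimental unit. Cells with fewer than 5 trials (a configurable minimum)
yield missing medians rather than unstable ones; the small dual-offer
low-value cell is the motivating case.

Within-session slowing is estimated by Huber IRLS regression of latency on
trial start time (tuning constant 1.345 standardized-residual units, MAD
scale re-estimated per iteration, convergence at a relative coefficient
change of 1e-8 or 200 iterations). When every standardized residual is
inside the threshold the estimate equals ordinary least squares; heavy
tails of the latency distribution otherwise receive bounded influence.

## The ex-Gaussian model

The ex-Gaussian is the convolution of a Normal(`mu`, `sigma`) and an
Exponential(mean `tau`); its mean is `mu + tau`, its variance
`sigma^2 + tau^2`, and its skewness `2 tau^3 / (sigma^2 + tau^2)^(3/2)`.
The density is evaluated in log space (the exponential prefactor combined
with `pnorm(..., log.p = TRUE)`) so the Gaussian limit `tau -> 0` does not
overflow. Fitting is single-shot maximum likelihood by bounded
quasi-Newton from a moment-based start (`tau0` from the sample skewness,
`mu0 = mean - tau0`, `sigma0^2 = max(var - tau0^2, eps)`), with a
Nelder-Mead fallback on the log scale when the line search fails near the
positivity bounds. We deliberately avoid bootstrap-averaged estimates: a
single deterministic fit is reproducible and the estimator is already
consistent at the per-cell sample sizes involved (>= 40 trials).

Each fit is validated by simulation: a synthetic sample of the same size is
drawn from the fitted parameters and compared with the raw data by a
two-sample Kolmogorov-Smirnov test; if that is significant at 0.05, a
Wilcoxon rank-sum test gives a second opinion, and the fit is accepted when
either test cannot distinguish generated from raw data. Matching the
synthetic sample size to the raw `n` maximizes the comparability of the KS
statistic. By construction this acceptance check passes about 95% of seeds
when the data truly come from the fitted model.

## The generalized drift-diffusion model

Evidence accumulates on `[0, a]` from a start point `z = a/2 + z0`, with
drift `v = k * log(lum_high / lum_low)` and diffusion noise `s`. The upper
boundary is the high-value choice. Three parameters are free:

| parameter | units | default box | meaning |
|---|---|---|---|
| `k` (drift coefficient) | evidence/s per log-contrast unit | 0.02-6 | stimulus sensitivity |
| `a` (boundary separation) | evidence units | 0.25-6 | evidence required to commit |
| `t0` (nondecision time) | s | 0-1 | sensory/motor latency |

Three constants are fixed: noise `s = 1.5`, start offset `z0 = 0.1`
(absolute evidence units toward the high boundary, so `a > 0.2` is
enforced), and a lapse mixture of weight 0.2 in which responses arrive from
a stimulus-independent exponential process (rate 1/s) with the choice at
random. Fixing `s` resolves the diffusion scale invariance — scaling
`(k, a, z0, s)` jointly leaves all choice probabilities unchanged, which
`choice_prob_closed_form()` verifies — and the lapse component keeps the
likelihood finite for latencies the diffusion process cannot produce. The
start offset is interpreted as an absolute offset because the reported
value (0.1) carries no units; with `a` near 2 this is a 5% bias toward the
high-value boundary. The lapse constant 0.2 is interpreted as the mixture
weight (not the exponential's rate); both constants are exposed as
arguments, so the alternative reading is one argument away.

First-passage densities come from two independent routes:

* **Analytic series** (`method = "series"`): the small-time image expansion
  and large-time Fourier sine series of the Wiener first-passage density,
  with the per-time-point switch and truncation chosen from the standard
  error bounds (absolute truncation error below 1e-6). This is the fast
  route used inside fitting.
* **Fokker-Planck PDE** (`method = "pde"`): Crank-Nicolson on at least 200
  interior space points with absorbing boundaries. The delta initial
  condition is allocated linearly to the two neighboring nodes; four
  implicit-Euler half steps (Rannacher smoothing) damp the spurious
  oscillations a delta excites under plain Crank-Nicolson, and the first
  output interval and early transient are integrated with internally
  refined time steps because the density rises steeply from zero. Boundary
  absorption uses the discrete flux that exactly telescopes the scheme's
  interior mass, so absorbed plus remaining probability is conserved to
  machine precision; space resolution scales with `noise/a` because the
  first-passage peak sharpens quadratically as boundaries narrow.

The two routes agree to an absolute density discrepancy below 1e-3 across
the tested `(k, a)` grid, and both match the closed-form absorption
probability to 1e-3; the test suite asserts all three tolerances. The
simulator (`simulate_ddm()`) is Euler-Maruyama with the exact
Brownian-bridge within-step crossing correction, which removes the
`O(sqrt(dt))` boundary bias of the naive scheme and makes `dt = 1e-3`
sufficient for 3-SE agreement with the closed form.

Fitting maximizes the summed log lapse-mixture likelihood by differential
evolution (rand/1/bin, population at least 15 per dimension, crossover 0.7,
scale factor dithered in `[0.5, 1)`, stop when the population's objective
spread falls below a tolerance), followed by a Nelder-Mead polish clipped
to the box; an estimate within 0.1% of a box edge raises a boundary
warning. Only dual-offer trials enter DDM fits — single-offer trials are
detection, not choice — and an optional 95th-percentile latency trim is
available as a configurable preparation step for outlier-sensitive fits.
Hierarchical Bayesian estimation is out of scope here; per-rat and pooled
maximum likelihood plus permutation tests on the per-rat estimates play
that role.

## Resampling statistics

*Paired permutation tests* sign-flip each pair's difference. When the
exhaustive null (`2^n` patterns) fits within the permutation budget it is
enumerated exactly; otherwise Monte-Carlo sampling uses the add-one
correction `p = (1 + #extreme)/(n_perm + 1)`, which keeps the p-value valid
(super-uniform) under the null. Confidence intervals are BCa from paired
bootstrap resamples (bias correction from the bootstrap distribution,
acceleration from the jackknife); with zero bias and acceleration the
interval reduces to the percentile interval. Defaults are 5,000 reshuffles
and 5,000 bootstrap samples.

*Repeated-measures ANOVA* is computed from the definitional within-subject
sums-of-squares partition on complete balanced designs, each effect tested
against its effect-by-subject interaction. Missing or unbalanced cells are
an error (the caller decides how to complete the design); no sphericity
correction is applied. The implementation is cross-checked in the test
suite against `aov()` with subject error strata.

*Repeated-measures correlation* is the ANCOVA estimator (subject-specific
intercepts, common slope), `r = sign(slope) * sqrt(SS_x/(SS_x + SS_err))`,
`df = n_obs - n_subjects - 1`, with the confidence interval from the
Fisher transform using `SE = 1/sqrt(df - 1)` — the convention that
reproduces the interval widths reported for this estimator elsewhere.

## What the synthetic cohort states, and what it does not

The generator is the analysis models run forward. Its defaults state the
emulated experiment: 15 rats, five sessions of 300 trials, one-third dual
offers, 8 vs 2 LEDs, 5% single-offer errors, right-skewed latencies with
medians near 0.5-0.65 s, and a dual-offer slowing of roughly 0.1 s that is
slightly larger for the low value. The generative learning effect is a
decision threshold declining linearly from 2.3 to 1.9 evidence units
across sessions with drift coefficient (0.8) and nondecision time (0.22 s)
fixed — the headline effect the pipeline is meant to recover. Dual-offer
choices and latencies are drawn from the DDM simulator; single-offer
latencies from per-value ex-Gaussians (high: mu 0.40, sigma 0.05, tau 0.11;
low: mu 0.43, sigma 0.06, tau 0.12, chosen so the low-value offer effect is
the larger one); within-session slowing adds 0.003 s of latency per minute
of session time (i.e., 5e-5 s/s, a slope the Huber regression can recover);
per-rat heterogeneity is log-normal multiplicative jitter (SD 0.12) on the
DDM free parameters and on mu and tau. The intertrial interval is a fixed
2 s plus an exponential of mean 2 s: the task is self-paced and no timing
distributions are published, so these are declared, not inferred — trial
start times and the within-session regression need *some* clock, and this
is the simplest one.

A green end-to-end test therefore establishes that the pipeline recovers
the stated generative structure — deliberative slowing, its decline, the
threshold effect, the drift-choice coupling — from data with realistic
sizes, mixtures, skew, and heterogeneity. It does not establish anything
about features the generator omits: side biases, satiety beyond linear
slowing, sequential dependencies between trials, session-to-session drift
in single-offer behavior, or deviations of real latencies from the
ex-Gaussian/DDM families. The 60-minute session length is also not
enforced; the simulated clock runs only as long as its 300 trials take.

## Numerical choices and degenerate inputs

* Trial tables round-trip exactly: floats are written with `%.17g`, so
  write-read-write is byte-identical and read-write is value-identical.
* Likelihood values are floored at 1e-12 before logging; latencies below
  `t0` have zero diffusion density and survive only through the lapse term.
* Ex-Gaussian fits refuse samples under 40 trials or with (near-)zero
  variance; validation requires a converged fit.
* Medians of groups below the configured minimum are missing values, and
  missingness propagates through offer effects rather than being imputed.
* Permutation tests with all-zero differences return `p = 1` and a
  degenerate `[0, 0]` interval; BCa clamps its bias correction away from
  infinite quantiles.
* The Huber loop treats a (near-)exact fit (MAD scale ~ 0) as converged
  OLS rather than dividing by zero; non-convergence is flagged on the
  result, not thrown.
* All stochastic stages derive child seeds deterministically from the
  master seed and a stage tag, so reports are reproducible end to end and
  no stage perturbs another's stream.

## Known limitations

* The DDM assumes a single stimulus condition per fit (the 8-vs-2 contrast
  of this task); multi-condition designs would need one first-passage
  solution per condition inside the likelihood.
* The luminance enters as LED counts because calibrated luminances are not
  available; only the log-contrast matters for the drift, so any common
  rescaling of the two stimuli is absorbed.
* Differential evolution with the default budget is stochastic-restart
  robust but not certified global; the boundary warning and the optimizer
  dominance check in the tests are the guardrails.
* `rm_anova` intentionally offers no sphericity correction and no
  unbalanced-design handling; designs must be completed or reduced first.
* Raw MedPC session files are not parsed; deposited data must be converted
  to the canonical CSV by the user before `replicate_from_deposited()`.
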