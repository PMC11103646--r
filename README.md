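# choicedyn

Analysis of how rats first learn to *choose*. In the underlying task
design, animals learn stimulus values on single-offer trials (one visual
cue, forced response: 8 LEDs → strong sucrose, 2 LEDs → weak sucrose) and
are then tested with interleaved dual-offer trials where both cues appear
and the animal chooses. The package is for behavioral and computational
neuroscientists who have trial-level latency/choice tables from such 2AFC
choice-learning experiments — or who want a fully synthetic cohort with the
same statistical structure — and need the complete analysis chain:
descriptive measures, latency-distribution and diffusion modeling, and
resampling inference.

## What it computes

**Deliberation.** Response latency is measured from trial initiation to the
side-port response; latencies above 3 s are screened out and error trials
are excluded from latency analyses. The *offer effect* — the dual-offer
minus single-offer difference of per-rat median latencies for the same
stimulus value — is the deliberation measure, tested per session with
paired sign-flip permutation tests (exhaustive when feasible, otherwise
5,000 reshuffles with the add-one correction), BCa bootstrap intervals
(5,000 resamples), and Bonferroni correction across sessions.

**Ex-Gaussian decomposition.** Latency distributions are modeled as
Normal(μ, σ) + Exponential(τ): μ indexes the sensorimotor peak, τ the
decision-variability tail (mean μ+τ, variance σ²+τ²). Fits are maximum
likelihood from moment-based starts, and each fit is validated by
generating a same-size synthetic sample from the fitted parameters and
testing it against the raw data (KS, then rank-sum on demand).

**Generalized drift-diffusion model.** Dual-offer choices follow evidence
accumulation on [0, a] from z = a/2 + z₀ with drift v = k·log(L_high/L_low)
and noise s; three free parameters (k, a, t₀) and three fixed constants
(s = 1.5, z₀ = 0.1, lapse mixture 0.2 with exponential rate 1/s). The
first-passage likelihood is computed from the analytic series expansion,
cross-validated against a Crank–Nicolson Fokker–Planck solver and a
bridge-corrected Euler–Maruyama simulator, and maximized by differential
evolution with a local polish. Pooled-per-session and per-rat fits feed
repeated-measures correlations with choice percentage and the ex-Gaussian
parameters — the analysis that shows drift tracking preference and the
decision threshold declining over early choice learning.

## Worked example

```r
library(choicedyn)

cohort <- generate_cohort(cohort_config(n_rats = 6, n_sessions = 2,
                                        trials_per_session = 300, seed = 42))
screened <- screen_latencies(cohort)

med <- median_latency(screened)
aggregate(median_latency_s ~ session_index + trial_type, med, mean)
#>   session_index trial_type median_latency_s
#> 1             1       dual        0.6598244
#> 2             2       dual        0.5574385
#> 3             1     single        0.5301918
#> 4             2     single        0.5325165

mean(choice_percentage(screened)$choice_pct)
#> [1] 74.2655
```

Dual-offer responses are ~0.13 s slower than single-offer responses in the
first choice session (deliberation), the gap narrows by session 2 while
single-offer latencies stay put, and the rats choose the high-value cue
~74% of the time.

```r
x <- screened$trials$latency_s[screened$trials$trial_type == "single" &
                               screened$trials$chosen == "high"]
validate_exgauss_fit(x, fit_exgauss(x), seed = 1)
#> Ex-Gaussian latency fit (n = 1131)
#>   mu = 0.4230 s, sigma = 0.0815 s, tau = 0.1157 s
#>   implied mean 0.5387 s, sd 0.1415 s; logLik 691.13
#>   validation: KS D = 0.019 (p = 0.983) -> accepted

dual <- subset(as.data.frame(screened), trial_type == "dual" &
               session_index == 1)
dual$choice <- dual$chosen
fit_ddm(dual, de_config = list(seed = 1))
#> DDM fit (pooled, n = 593 trials)
#>   k = 0.9749, a = 2.5532, t0 = 0.2460 s; logLik = -644.23
```

The ex-Gaussian splits the single-offer distribution into a 0.42 s
sensorimotor peak and a 0.12 s exponential tail, and the session-1 DDM fit
recovers a high decision threshold (a ≈ 2.6) — the quantity that declines
as choice learning progresses.

`run_pipeline(pipeline_config(simulate = default_config(), seed = 1))` runs
the whole chain (metrics → ex-Gaussian → DDM → permutation tests → rmANOVA
→ rm-correlations) on the default 15-rat, five-session cohort and returns
an `analysis_report`; `write_report()` serializes it to CSVs plus
`report.json`. A thin CLI (`exec/choicedyn`) exposes `simulate`, `metrics`,
`fit-exgauss`, `fit-ddm`, `stats`, `run`, and `replicate` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full default-cohort analysis from scratch — simulation,
screening, metrics, both model-fitting layers, and the resampling
statistics — prints the report summary, and writes the acceptance JSON to
`--out`.

## Replicating from deposited data

`replicate_from_deposited(path)` runs the identical pipeline on a
user-converted canonical trial CSV (raw MedPC session files are not
parsed; see `?read_trial_table` for the column contract) and attaches a
comparison table against the published cohort-level reference values the
pipeline was designed around. With fewer than three subjects the
comparison is marked `insufficient n` instead of computed.
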