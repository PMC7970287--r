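---
title: "Analysing three-arm cluster-randomised child development trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing three-arm cluster-randomised child development trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdtrial)
library(dplyr)
```

`ecdtrial` implements the statistical machinery of a three-arm,
village-randomised trial of an integrated early child development (ECD)
intervention: two active delivery arms (group sessions, and group sessions
combined with home visits) against an oversized control arm, with villages
as clusters, stratified by subdistrict. This vignette is the package's own
account of the models and the decisions behind them.

## The estimation model

The primary analysis is intention-to-treat. For each outcome and each
treatment arm versus control, the package computes an **adjusted mean
difference** (continuous outcomes) or **prevalence difference** (binary
outcomes) by *parametric g-computation*, also called marginal
standardisation:

1. fit the outcome regression on the two compared arms —
   linear `y ~ arm + covariates` for continuous outcomes, logistic for
   binary ones;
2. predict every analysed record's outcome twice, once with `arm` set to
   treatment and once with `arm` set to control;
3. report the difference of the two prediction means, on the outcome
   scale (probability scale for binary outcomes).

For a linear model with no treatment–covariate interaction this equals
the fitted arm coefficient (collapsibility); for logistic models it does
not equal any single coefficient, which is exactly why the marginal
standardisation step matters. `gcompute()` is checked against a
brute-force counterfactual loop (edit every record's arm, `predict()`,
average) to 1e-10 in the test suite.

Covariates enter through a prescreen (`prescreen_covariates()`): for each
registered candidate — parental education, child age, child sex, household
income (median split), wall material, assets, electricity, the baseline
measure of the outcome, and interviewer for child development and home
observation outcomes — the model with and without that single candidate
(both containing the arm indicators) is compared by a likelihood-ratio
test, and candidates with p < 0.20 are retained. The nesting (arm always
present, candidates tested singly) is our choice; the screen runs once on
the original data and the retained set is frozen across bootstrap
replicates, because re-screening inside replicates would change the
estimand.

Confidence intervals come from a **village-clustered bootstrap**
(`cluster_bootstrap()`): clusters are resampled with replacement,
*stratified within arm* so every replicate keeps the design's arm-wise
cluster counts, the estimator is re-run on the stacked records, and the
2.5th/97.5th percentiles of 1000 replicate estimates (400 in the
calibration experiments) are reported. Percentile limits were chosen over
BCa as the simplest method consistent with resampling whole villages. No
multiplicity adjustment is applied: each outcome yields one comparison
per treatment arm.

## Age-standardisation of development scores

Child development raw scores (five ASQ-inventory domains, their raw-sum
total, and the CDI word counts) are **internally age-standardised to the
control arm**: `fit_standardizer()` estimates age-conditional means and
SDs from control-arm, followed-up records only, and `standardize()`
z-scores all arms against those norms. Records with |z| > 4 are excluded,
two-sided, per outcome independently — which is why the analysed n
differs across development outcomes. The total score is summed across
domains on the raw scale *before* standardisation.

The default estimator bins age in 3-month windows, merging bins below 15
control records with their neighbour; a quadratic-mean/linear-SD
regression method is the alternative. Binning was preferred as the
default because it is transparent, assumption-light and easy to audit
(`tidy()` returns the bin table; `write_standardizer_yaml()` serialises
it). Standardisers are fitted once on the original sample and reused
inside bootstrap replicates, keeping the estimand fixed norms rather than
replicate-varying ones.

Self-standardisation is exact in one direction by construction: within
each bin the control z-scores have mean 0; the pooled control SD is
slightly below 1 (about `sqrt((N - k)/(N - 1))` for k bins), which at
n≈280 and 7 bins is within 1% of 1.

## Instrument scoring

Scoring is strict and dictionary-driven (`inst/extdata/instruments.yaml`):

* **FCI** — stimulating-activities count (0–6, primary-caregiver
  respondent by default, with an `any_adult` variant), play-material
  varieties (0–6), and an 11-item responsiveness/home-environment
  observation sum (0–11).
* **ASQ inventory** — per-domain raw = sum of item scores under the
  yes = 10 / sometimes = 5 / not yet = 0 convention. The adapted
  inventory's item count per domain is not public; 6 items per domain
  (0–60, consistent with published domain means of 50–59) is the
  configurable default.
* **CES-D** — 20 items, 0–3, positively-worded items 4/8/12/16
  reverse-coded per the standard key, total 0–60.
* **CDI** — endorsed-word counts; the real adapted Bangla word list is
  not public, so the dictionary ships a synthetic 100-word inventory per
  domain. Expressive vocabulary is only defined over 9 months of age.
* **Dietary diversity** — maternal MDD-W: at least 5 of 10 food groups;
  child: at least 5 of 8 counting breastmilk. Child MDD is only defined
  over 6 months.

Missing required items make the score missing — no pro-rating or
imputation anywhere.

## Design calculations

`design_effect(m, icc)` is `1 + (m − 1)ρ`; `crt_power()` is the
normal-approximation power of the two-sided two-sample test with standard
error `sd · sqrt(DE · (1/(k_t m) + 1/(k_c m)))`. With a mean difference
of 2.0, SD 3.3, ρ = 0.20, 20 participants per cluster and α = 0.05, the
8-treatment / 15-control village design gives power 0.807:

```{r power}
crt_power(delta = 2.0, sd = 3.3, icc = 0.20, m = 20,
          k_treatment = 8, k_control = 15)
required_clusters()
```

The normal approximation is the default because it reproduces this
published design from its stated inputs; `df_method = "t"` substitutes
cluster-level degrees of freedom and is more conservative.
`randomize_villages()` performs the stratified 5:5:8 / 3:3:7 allocation,
and `screen_villages()` applies the 1.5-SD demographic eligibility rule.

## The synthetic trial generator

`simulate_trial()` emulates the data structure the analysis assumes — it
is the package's test bed, not a model of any real village. Continuous
outcomes follow a village random-intercept model

y_ij = μ + β_age · age_ij + effect(arm) + u_j + e_ij,  u_j ~ N(0, ρσ²), e_ij ~ N(0, (1−ρ)σ²),

so a fraction ρ (default 0.20) of the non-age outcome variance is
between villages; binary outcomes use a logistic-normal village
intercept, with ρ interpreted on the latent logistic scale (the design
ICC is stated only for the continuous power calculation). Scores are
clipped and rounded onto instrument supports, ages are uniform on 4–26
months at endline, attrition (default 7.6%) is completely at random, and
the default allocation is the 31-village 5:5:8 + 3:3:7 design with 20
participants per village. Default treatment effects are zero — the null
trial is the baseline condition for the calibration experiments, and
recovery experiments set effects explicitly. Control-arm locations and
spreads follow the published endline control summaries; baseline
covariate frequencies follow the published baseline table, but their
joint distribution is invented (the source reports only marginals), and
baseline–endline correlation (0.3) for the outcomes measured at both
waves is a realistic invention too.

With `items = TRUE` the generator also emits item-level instrument
responses constructed to be exactly consistent with each generated score,
which gives the scoring module a strong round-trip oracle: scoring the
items must reproduce the generated score columns bit for bit.

Two things the generator deliberately does *not* emulate: informative
attrition (a covariate-dependent mechanism can be configured, but MCAR is
the default since observed loss did not differ by arm), and within-village
sampling quirks (enrolment is exactly clusters × 20; the realised trial
had one extra participant). Passing tests therefore speak to the
estimators under clean clustered sampling, not to robustness against
informative missingness.

### Ceiling effects and the recovery experiment

On a 0–6 scale with control mean 3.2 and SD 1.5, adding a treatment
effect of 1.56 pushes roughly a fifth of treated scores past the ceiling;
censoring then attenuates the ITT contrast by about 0.25 points. That is
a property of the instrument, not an estimator defect, so the
parameter-recovery experiment (effect 1.56 recovered within Monte-Carlo
error at 200 clusters) runs with `bound_scales = FALSE`, targeting the
uncensored additive estimand. Analysts should expect the same attenuation
in real bounded instruments.

## Calibration results and a known limitation

The test suite calibrates the whole pipeline on 500 simulated null trials
of the default design (31 villages × 20, ρ = 0.20), with 400-replicate
bootstrap CIs. Measured over those runs, the percentile cluster-bootstrap
95% CI covers the true null in about 91% of trials, and the full
screen → g-compute → bootstrap pipeline rejects in about 9% — short of
the nominal 95%/5%. This is the well-documented small-sample behaviour of
the with-replacement cluster bootstrap: with only 8 treatment villages,
replicate variance understates sampling variance by roughly (k−1)/k per
arm, and percentile limits add further error. The same machinery reaches
94% coverage when the simulated design has 50 clusters per arm, which is
why we attribute the shortfall to the design's cluster count rather than
to the implementation. Practically: with so few clusters per arm,
percentile bootstrap CIs should be read as slightly anti-conservative;
the original analysis, which used the same interval type at the same
cluster counts, shares this caveat.

Problem sizes used by the test suite — 500 null trials × 400 replicates
for calibration, 30 trials of 200 clusters for recovery, 400 replicates
for the prescreen-retention check — were chosen to keep Monte-Carlo error
comfortably inside each acceptance band.

## Worked example

```{r pipeline}
trial <- simulate_trial(sim_config(
  seed = 1,
  outcome_effects = list(fci_activities = c(group = 1.0, combined = 1.5))))

trial <- trial |>
  score_trial() |>
  standardize_scores("asqi_communication")

specs <- bind_rows(
  outcome_spec("fci_activities"),
  outcome_spec("asqi_communication", standardized = TRUE),
  outcome_spec("lead_knowledge", scale = "binary"))

effects <- estimate_effects(trial, specs, B = 200, seed = 7)
tidy(effects)
results_table(effects, trial)
consort_flow(trial)
```

`autoplot(effects)` draws the forest plot; `adjusted_means()` reproduces
the age-adjusted per-arm means layout used for primary-outcome reporting.

## Numerical notes

* Ages outside the fitted standardiser range are clamped to the boundary
  bin; zero within-bin variance is an error, not a silent division.
* `gcompute()` refuses non-converged logistic fits and flags suspected
  separation (|coefficient| > 20) instead of returning garbage; inside
  the bootstrap such replicates are redrawn, with more than 5% failures
  an error.
* Aliased model columns (e.g. a factor level absent from a bootstrap
  replicate) are dropped from prediction, matching `lm()`'s convention.
* Display rounding (`round_half_up()`) rounds halves away from zero —
  table conventions, applied at render time only; stored values are
  never rounded.
* All randomness is seed-controlled: the generator takes a seed, and a
  run-level seed fans out deterministically to per-outcome bootstrap
  streams, so a manifest (`run_manifest()`) pins down a bit-for-bit
  re-run.
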