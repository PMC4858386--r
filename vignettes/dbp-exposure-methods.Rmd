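---
title: "Modelling DBP exposure in pregnancy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DBP exposure in pregnancy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpexposure)
```

This vignette explains the models behind `dbpexposure`, the assumptions they
make, the parameters a user may want to change, and where the design was
genuinely open and a choice had to be made.

## 1. Concentration surfaces from sparse monitoring

Routine utility monitoring gives a handful of samples per water supply zone
(WSZ) per year; exposure assignment needs a concentration for *every* zone
and month (THMs) or quarter (HAAs). The package therefore fits predictive
regressions and evaluates them on a complete grid.

**THMs.** Concentrations are modelled on the log scale,

$$\log c_{zym} = \beta_0 + s(m) + \gamma_y + \delta_z + \varepsilon,$$

with $s(\cdot)$ a spline in month of year (seasonality), $\gamma_y$ a factor
per calendar year and $\delta_z$ a factor per zone. Samples below the limit
of detection enter at LOD/2 (`substitute_half_lod()`); bromoform is so
heavily censored that it is never modelled alone — the brominated sum THMBr
(BDCM + DBCM + bromoform, summed at the sample level by `derive_thmbr()`) is
modelled instead.

*Spline basis.* The degrees of freedom are not dictated by theory; the
default is a natural cubic spline with 4 df for month (3 df for the
quarterly HAA time spline), enough to track one seasonal rise and fall
without chasing noise in ~47 samples per zone. Because a natural spline is
not periodic, December and January need not join smoothly; `cyclic = TRUE`
switches to a Fourier (sin/cos) basis when a periodic seasonal shape is the
better assumption. The default stays non-cyclic: real seasonal patterns need
not be periodic across the year boundary (e.g. a cold snap spanning
December–January only on one side).

*Back-transformation.* Predictions are naive back-transforms
($\exp(\hat\eta)$, or $\hat\eta^2$ for square-root models) by default, which
estimate the median rather than the mean on the concentration scale; Duan's
smearing correction is available (`smearing = "duan"`) for the log-scale
models. The naive default keeps the estimator simple and the bias is ~1% at
the residual variances seen here; the choice is exposed rather than hidden.

**HAAs.** DCAA and TCAA are modelled on the square-root scale, BDCAA on the
log scale, each with a WSZ factor, a natural spline over continuous quarter
index, and a fixed analyte-specific covariate set: conductivity (all three),
temperature (DCAA, TCAA), TOC (TCAA), total chlorine (BDCAA). These sets are
*not* re-selected at fit time; re-running variable selection on every
synthetic dataset would make the model family itself random.

The `bayesian` mode re-expresses the same linear structure in JAGS with
weakly informative priors — Normal(0, 100²) on coefficients, half-Normal(5)
on the residual scale, covariates standardized before sampling — and gives
each covariate a Normal population submodel so that missing covariate
entries become latent nodes imputed within the posterior. That is also how
cells with *no* samples are predicted: a withheld quarter (an anomalous lab
batch, say) or a one-step extrapolation quarter has its covariates imputed
from the population model and its mean drawn through the regression.
Convergence is checked with the Gelman–Rubin statistic over two chains
(threshold R-hat < 1.05; a failure is flagged with a warning, not silently
accepted). Posterior surfaces are back-transformed per draw, so predictions
are posterior means on the concentration scale and strictly positive by
construction.

`build_surface()` stamps every cell with provenance — `fitted`,
`gap_filled` (withheld from training) or `extrapolated` — and refuses
extrapolation more than one grid step beyond the training window: a spline
extrapolates linearly at best, and one quarter is as far as we trust it.

## 2. From surfaces to per-pregnancy exposure

Gestational windows use fixed day cuts: trimester 1 is days 1–93, trimester
2 days 94–186, trimester 3 day 187 to the day before delivery; the whole
pregnancy runs from day 1 to the day before delivery. Time weights are the
fraction of window days falling in each calendar month/quarter; they are
nonnegative and sum to one, and the test suite checks them against a
brute-force day-by-day oracle to 1e-9.

Women with an assigned workplace zone get a 72/112 residence + 40/112
work blend (8 h at work, 5 days a week, of 112 waking hours); all others get
the residence zone alone. A window that extends outside surface coverage
yields a *missing* metric, never zero — e.g. HAA metrics are missing for
pregnancies that begin before the HAA surface starts.

Ingestion multiplies the TWA concentration by adjusted daily tap-water
volume. The adjustments are the published fractional changes: boiling (hot
beverages, i.e. tea + coffee) THMs −92%, DCAA +43.5%, TCAA −36.9%, BDCAA
−56.5%; filtering (cold tap component only, when a home filter is used)
THMs −90%, DCAA −61.8%, TCAA −67.4%, BDCAA −78.5%. Squash is always
unfiltered, and bottled water contributes nothing. One genuinely open corner:
when a home filter is present, is the hot-beverage volume filtered *and*
boiled? The two factors are applied to disjoint drink classes here (boiling
to hot beverages, filtering to cold tap), matching the way the adjustment
factors were defined; users combining both should know the package never
stacks them.

Integrated THM uptake sums four pathways: ingestion, showering, bathing
(tap TWA × minutes/day × uptake factor) and swimming (pool concentration ×
minutes/day × factor). Activity minutes are divided by 7 because the
questionnaire reports minutes/week and uptake is a daily dose. **The pathway
uptake-factor magnitudes shipped as defaults are synthetic placeholders**:
the biomonitoring-derived values they stand in for are not reproduced here,
so `uptake_factor_table()` documents its provenance field as
`synthetic-default` and the defaults were chosen once to land integrated
whole-pregnancy TTHM uptake near the 1–2 µg/day scale reported for UK
cohorts. Real analyses should supply measured factors. The same applies to
the single pool TTHM concentration (33 µg/L), apportioned to individual THMs
by typical tap-water composition.

Tertiles are cut at the 1/3 and 2/3 sample quantiles of the analysis
population with lower-closed intervals and a closed top tertile (a value
equal to the upper cutpoint is "high", matching the ≥ convention); fixed
water-use categories use the questionnaire bin edges. Missing values get
missing categories — silently binning a missing exposure would fabricate
person-time.

## 3. Cohort assembly

`apply_exclusions()` applies the eligibility cascade in a fixed order:
singleton births; one pregnancy per mother (uniform random choice under a
caller-supplied seed — the selection is reproducible bit-for-bit);
water-use data present; THM exposure computable for all trimesters
(operationalized as every trimester window inside surface coverage, or a
precomputed flag); birth weight present; term delivery at ≥ 37 completed
weeks. The order matters — the same flags applied in a different order give
different stage counts — so the function owns the order and logs each stage.
Model fitting is complete-case per covariate set (`complete_case()`); no
imputation of maternal covariates is attempted, matching the analysis the
pipeline emulates.

## 4. Birth-weight regression

The outcome is continuous birth weight in grams. Exposure enters as a
tertile factor (or two factors in the joint model: DBP7 ingestion via
consumption plus TTHM uptake via showering/bathing/swimming — ingestion is
the dominant HAA route, so the joint metric is built that way, with the
volatile non-ingestion remainder as a separate term). Adjustment covariates
are fixed a priori: caffeine ≥ 200 mg/day, education (5 levels), fasting and
post-load glucose, ethnicity, smoking (3 levels), parity (0/1/≥2), age, BMI
quartile, IMD deprivation quintile, plus gestational age (linear and
quadratic — birth weight flattens near term) and infant sex. Ethnic-stratum
models drop the ethnicity covariate. BMI quartiles (and exposure tertiles)
are computed within the analysis population, not from external reference
values.

Inference is classical OLS: t-based Wald CIs (no robust SEs — none are
assumed by the emulated design), an F-test for the exposure factor as a
whole, a trend test refitting with tertiles coded 0/1/2 as a continuous
term (a literal refit, not a contrast within the factor fit, so the reported
p is exactly the stated procedure), and a joint F-test over exposure ×
ethnicity products in the total-population model. Two-sided α = 0.05, no
multiplicity correction. The test suite verifies OLS against a
normal-equations oracle to 1e-8 and checks that all three tests hold their
nominal size within 5% ± 1.5 points over 1,000 seeded null replicates.

## 5. The synthetic-data generator, and what passing tests mean

`scenario_config()` fixes the study conditions: 8 zones; ~9 THM samples per
zone-year over January 2006–March 2011 (~376 TTHM points); quarterly HAA
samples June 2007–November 2010; a raw register of 13,525 babies whose
cascade rates leave ~9,200 eligible; ethnicity mix 40/45/15 (white British /
Pakistani origin / other); ethnicity-specific water use targeting total tap
1.84 vs 1.51 L/day, bathing 151 vs 96 min/week, showering 86 vs 94 min/week,
swimming participation 14% vs 2%; concentration targets TTHM 45.6, DCAA 8.9,
TCAA 12.5, BDCAA 1.3 µg/L; term birth-weight baselines 3,424 / 3,186 g with
residual SD 450 g.

The distributional *forms* are the package's own choices: log-normal
concentrations with a sinusoidal season and fixed zone offsets; gamma water
volumes and activity minutes with Bernoulli participation; MCAR missingness.
Water-use behaviours are drawn independently within woman (real consumption
and bathing surely correlate; the scenario config leaves that correlation at
zero because no target value is available). Covariate effects on birth
weight are a plausible fixed vector (e.g. +120 g male sex, −180 g current
smoking, +140 g per gestational week near term). The exact-cascade fixture
(`make_cascade_fixture()`) is deterministic by construction: each
repeat-pregnancy mother has exactly two pregnancies with identical
downstream flags, so the seeded one-per-mother draw cannot change the stage
counts.

Recovery studies (`recover_tertile_effect()`) plant known tertile effects in
a simulated Pakistani-origin stratum of n = 3,298 and re-estimate them 100
times. The exposure metrics are deliberately confounded with smoking, age
and parity (shifting the metric's location by up to ~15% for smokers), so
the crude and adjusted estimates differ and the adjustment is genuinely
exercised; because the confounders are in the model, recovery remains
unbiased and 95% CI coverage sits at its nominal level. Problem sizes
(100 replicates, n = 3,298; 1,000 null replicates at n = 250 for test size)
were chosen so the whole validation runs in well under a minute while Monte
Carlo SEs stay below 2.5 g.

What passing these tests shows: the pipeline's arithmetic is right, its
estimators are unbiased under the assumed generative forms, and its tests
hold their size. What it does *not* show: that real monitoring data follow a
log-linear seasonal model, that questionnaire water use is accurately
recalled, that the placeholder uptake factors are biologically correct, or
that residual confounding (diet, stress, personal-care products) is absent
in any real cohort. Real-data estimates also reflect residential mobility
and geocoding error, both outside this package's scope.

## 6. Numerical and degenerate-input behaviour

- Half-LOD substitution never raises a value above its LOD and never touches
  detected samples; censored samples without an LOD are an error.
- Surfaces are strictly positive by construction (back-transform from
  log/sqrt scales); a non-positive prediction is an error, not a warning.
- Singular designs (too few samples, aliased covariates) fail with the
  offending terms named, before any silent NA coefficients propagate.
- A pregnancy window outside surface coverage yields `NA` metrics with the
  cascade flagging the record, never a zero.
- Tertile ties: both cutpoints equal puts the tied value in the top
  category (closed-top convention).
- Empty windows (delivery before gestational day 187 for trimester 3) raise
  an error at window construction, not downstream.
- Bit-identical reruns under a fixed seed use R's default Mersenne-Twister
  RNG; the Bayesian mode seeds both JAGS chains explicitly.
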