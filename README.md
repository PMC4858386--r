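# dbpexposure

Chlorination of drinking water produces disinfection by-products (DBPs), most
prevalently trihalomethanes (THMs: chloroform, BDCM, DBCM, bromoform) and
haloacetic acids (HAAs: here DCAA, TCAA, BDCAA). Epidemiological studies of
DBPs and fetal growth must bridge a large gap: water utilities measure
concentrations sparsely per water supply zone (WSZ), while the quantity of
interest is each pregnant woman's dose over her pregnancy, which depends on
where she lives and works, how much tap water she drinks, whether she boils
or filters it, and how long she showers, bathes and swims.

`dbpexposure` implements that whole chain as a tested R pipeline for
environmental epidemiologists:

1. **Concentration modelling** — sparse monitoring records are turned into
   complete zone-by-time concentration surfaces. Log-transformed THMs are
   modelled by OLS with a spline in month, a year factor and a WSZ factor
   (monthly surfaces); square-root-transformed DCAA/TCAA and log-transformed
   BDCAA are modelled with a WSZ factor, a spline over quarter and
   analyte-specific water-chemistry covariates, either by OLS or in a
   Bayesian (JAGS) formulation that imputes missing covariates and gap-fills
   withheld or extrapolated quarters (quarterly surfaces). Values below the
   limit of detection enter at LOD/2.
2. **Exposure assessment** — per pregnancy and gestational window (whole
   pregnancy, trimesters with day cuts 1–93 / 94–186 / 187–delivery-1):
   time-weighted average (TWA) concentrations with weights proportional to
   days of overlap per month/quarter and a 72/112 residence + 40/112 work
   blend for women with an assigned workplace zone; ingestion (µg/day) with
   published boiling adjustments (THMs −92%, DCAA +43.5%, TCAA −36.9%,
   BDCAA −56.5%) and filtering adjustments (THMs −90%, DCAA −61.8%,
   TCAA −67.4%, BDCAA −78.5%); pathway-resolved and integrated blood uptake
   of THMs (ingestion + showering + bathing + swimming, pools at pool
   concentrations); and the aggregates THMBr, HAA3 and DBP7.
3. **Cohort assembly** — the eligibility cascade (singleton → one pregnancy
   per mother, seeded → water-use data → THM exposure computable → birth
   weight present → term birth) with a stage-by-stage log, and complete-case
   restriction per model.
4. **Regression** — OLS on continuous birth weight with tertile exposure
   factors (reference = lowest), adjusted for ten a-priori maternal factors
   plus gestational age (linear + quadratic) and sex; ethnicity-stratified
   fits; F-test for the exposure factor, trend test with tertiles coded
   0/1/2, and a joint F-test for exposure × ethnicity interaction; a joint
   two-exposure model (DBP7 ingestion + shower/bath/swim TTHM uptake).
5. **Synthetic data** — a generator emulating the study conditions (8 WSZs,
   ~9 THM samples/zone/year 2006–2011, quarterly HAAs, a ~13,500-record
   register with a multi-ethnic cohort and ethnicity-specific water use), so
   every step above is testable by parameter recovery.

## Worked example

```r
library(dbpexposure)

cfg <- scenario_config(seed = 1)
mon <- simulate_monitoring(cfg)                       # 8 zones, 2006-2011
tthm <- fit_concentration_surface(mon, "TTHM", "month")
tthm$model
#> THM concentration model: TTHM
#>   log scale; month spline df 4 (natural)
#>    8 zones, 6 years, 376 samples; residual sd 0.133

head(tthm$surface, 3)
#>   analyte wsz_id time_cell pred_ugL       sd provenance
#> 1    TTHM   WSZ1   2006-01 34.62533 1.238006     fitted
#> 2    TTHM   WSZ2   2006-01 34.86569 1.211733     fitted
#> 3    TTHM   WSZ3   2006-01 36.30467 1.209213     fitted

# whole-pregnancy TWA for a woman living in WSZ3, working in WSZ7
win <- exposure_window("whole", as.Date("2008-03-01"), as.Date("2008-11-25"))
twa <- twa_concentration(tthm$surface, win, residence_wsz = "WSZ3",
                         work_wsz = "WSZ7")
round(twa, 2)
#> [1] 48.51

# integrated blood uptake for her water-use profile
prof <- water_use_profile(tap_Lday = 1.2, tea_Lday = 0.6,
                          shower_minwk = 90, bath_minwk = 60)
up <- integrated_uptake(prof, c(TTHM = twa), uptake_factor_table())
round(up$integrated, 3)   # ug/day total blood dose
#>  TTHM
#> 2.034
```

The TWA (48.5 µg/L) is the day-weighted, work/residence-blended mean of the
modelled monthly zone concentrations over her pregnancy; the integrated
uptake (2.03 µg/day) sums the ingestion (0.45), showering (1.00) and bathing
(0.58) pathway doses — showering and bathing dominate, as expected for
volatile THMs.

Validation by parameter recovery: plant a −53.7 g top-vs-bottom tertile
effect of TTHM uptake in a simulated Pakistani-origin stratum (n = 3,298)
and re-estimate it with the adjusted model, 100 times:

```r
recover_tertile_effect("tthm_uptake", n = 3298, reps = 100, seed = 1)
#> Recovery study: tthm_uptake - 100 replicates
#>   truth -53.7 g; mean recovered -53.3 g (MC SE 1.96); 95% CI coverage 96%
```

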