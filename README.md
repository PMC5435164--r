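# ssbtax

Simulation of the health impact of Mexico's sugar-sweetened beverage (SSB)
excise tax on adult body weight, obesity prevalence and diagnosed type-2
diabetes.

In January 2014 Mexico introduced a one-peso-per-litre excise tax on
beverages with added sugar (≈10% of shelf price). Purchase data attributed
an average 6.1% reduction in taxed-SSB purchases to the tax in 2014,
with larger effects in low socioeconomic-status (SES) households
(−9.1% / −5.6% / −5.5% across SES tertiles) and a peak monthly effect of
11.9% (−17.4% / −13.1% / −6.8%). `ssbtax` chains these observed demand
shocks through mechanistic health models to project what they imply for
population weight and diabetes, for epidemiologists and health-policy
modellers who want a fully reproducible, data-free (synthetic-population)
version of that analysis.

## What the package computes

1. **Synthetic survey population** — adults (20+) with sex, age, height,
   weight, SES tertile, taxed-SSB consumption (zero-inflated log-normal,
   calibrated to a population mean of ~323 ml/person/day with quartile cut
   points near 33.9/129.6/402.9 ml/day) and survey expansion weights.
2. **Tax scenarios** — four registered scenarios (`avg10`, `peak10`,
   `avg20`, `peak20`); the 20%-tax scenarios double the SES-specific
   reductions. Volume changes convert to energy at 0.388 kcal/ml.
3. **Dynamic weight change** — the Chow–Hall energy-balance ODE per
   individual: the intake perturbation partitions between fat and lean
   tissue along the Forbes curve `p(F) = C/(C+F)`, with expenditure
   `E = K + γ_F F + γ_L L + δ·BW + TEF + adaptive thermogenesis +
   deposition costs`, plus glycogen and extracellular-fluid transients.
   Everyone is sedentary (PAL 1.5); BMI is reported at 1 and 10 years.
4. **BMI outcomes** — WHO categories (normal < 25, overweight 25–29.99,
   obese ≥ 30 kg/m²), survey-weighted prevalence and stratified mean BMI
   changes.
5. **Diabetes projection** — a multi-cohort Markov state-transition model
   (no diagnosed diabetes → diagnosed diabetes → dead) on an age × sex ×
   SES grid, 2015–2050, under optimistic/intermediate/pessimistic
   incidence scenarios. The tax enters as a counterfactual incidence
   multiplier `RR^Δservings` with RR = 1.26 per daily serving
   (95% CI 1.12–1.41).
6. **Comparative risk assessment** — linear BMI-per-serving coefficients
   (0.11–2.12 kg/m² per serving/day) as a sensitivity bracket on the ODE
   result.

## Worked example

```r
library(ssbtax)

pop <- generate_population(population_config(n = 10000, seed = 1))
pop
#> <ssb_population> 10000 adults
#>   weighted mean SSB: 314.2 ml/day; weighted mean BMI: 28.48 kg/m2

ch <- apply_tax(pop, "avg10")          # 10% tax, average 2014 effect
summarize_consumption(pop, ch, strata = "overall")[,
  c("baseline_ml_mean", "baseline_kcal_mean", "delta_ml_mean", "delta_kcal_mean")]
#>   baseline_ml_mean baseline_kcal_mean delta_ml_mean delta_kcal_mean
#> 1           314.23             121.92        -21.46           -8.33

panel <- simulate_cohort(pop, ch$delta_kcal, at_years = c(1, 10))
stratified_bmi_change(pop, panel, t = 10, strata = c("overall", "ses"))
#>      stratum baseline_bmi bmi_reduction pct_change
#> 1    overall       28.479         0.164      0.574
#> 2    ses:low       28.457         0.235      0.826
#> 3 ses:medium       28.534         0.132      0.464
#> 4   ses:high       28.446         0.124      0.436

base <- project_diabetes()             # intermediate incidence, no tax
cf   <- project_diabetes(link = risk_link(ses_mean_servings_change(pop, ch)))
round(averted_cases(base, cf, c(2030, 2050)) / 1000)   # thousands
#> 2030 2050
#>  119  269
```

Reading the numbers: a 6.1%-average purchase reduction removes ~21 ml
(~8.3 kcal) per person per day, which the energy-balance model turns into
a mean BMI reduction of ~0.16 kg/m² after 10 years — largest in the
low-SES tertile, whose purchase response was strongest. Feeding the same
consumption change into the diabetes model averts roughly 119 thousand
diagnosed cases by 2030 (269 thousand by 2050) relative to the no-tax
projection.

The whole chain, including report CSVs and a reproducibility manifest, is
one call:

```r
run_pipeline(run_config(seed = 1), outdir = "out/")
```

## Repository layout

- `R/` — generator, tax scenarios, Chow–Hall ODE (vectorised RK4), BMI
  tables, Markov projection, CRA sensitivity, pipeline orchestration.
- `tests/testthat/` — unit, property and end-to-end suites, including
  fine-step Euler and `deSolve` oracles for the ODE and pencil-and-paper
  and microsimulation oracles for the Markov model.
- `vignettes/ssb-tax-methods.Rmd` — model equations, calibration choices
  and limitations.
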