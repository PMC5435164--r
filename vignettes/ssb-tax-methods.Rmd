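---
title: "Methods: from an SSB tax to weight, obesity and diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from an SSB tax to weight, obesity and diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

`ssbtax` chains four models: a synthetic survey-population generator, an
SES-stratified consumption shock, the Chow–Hall dynamic energy-balance
model of individual weight change, and a multi-cohort Markov projection of
diagnosed diabetes. This vignette states each model, its assumptions, the
tunable parameters and their defaults, the calibration decisions, and what
the synthetic population can and cannot tell you about real survey data.

## The synthetic population

Real applications of this analysis use restricted national survey
microdata. The generator replaces that input with a synthetic population
whose *marginals* match the published ones, so the full pipeline is
testable and reproducible without any data access.

Each of `n` adults receives:

* **sex** (44.87% male), **age group** (47.21% aged 20–39, 34.20% aged
  40–59, 18.59% aged 60+, uniform within bands, the open band truncated
  at 90), and **SES tertile** (33.65/32.91/33.43, renormalised);
* **height**: sex-specific normal (men 1.65 ± 0.07 m, women 1.53 ±
  0.065 m — synthetic conventions chosen as plausible for Mexican adults,
  not published values);
* **BMI**: normal within sex × age group, means from the published
  baseline table (overall weighted mean ≈ 28.4 kg/m²), SD 4.5 kg/m²,
  redrawn into [16, 55]; weight is `BMI · height²`;
* **taxed-SSB consumption** (ml/person/day): zero with probability
  `p0 = 0.2035`, otherwise log-normal with `meanlog = 5.3305`,
  `sdlog = 1.1557`, multiplied by an SES factor (1.08/1.00/0.92) and an
  age-group factor (1.25/0.8725/0.60), each share-weighted to ≈ 1;
* **expansion weight**: log-normal with unit mean (`sdlog` 0.3).

### Calibrating the consumption distribution

The published marginals are a mean (SD) of 323.49 (520.44) ml/day and
quartile cut points 33.94 / 129.64 / 402.86 ml/day. No zero-inflated
log-normal reproduces all five numbers: matching mean and SD exactly
forces the median boundary ~30% high, and matching the three quartiles
exactly forces the mean ~55% high — real consumption data are not
log-normal in the tails. We therefore calibrated `(p0, meanlog, sdlog)` by
weighted least squares, prioritising the mean (the quantity all
downstream per-capita results scale with) and the quartile boundaries,
and letting the SD absorb the conflict. The frozen defaults imply a mean
of ~321 ml/day (−0.8%), quartile boundaries within ±10% of the published
cut points, and an SD ~20% above the published one. Sampled populations
of n = 10,000 land within ~3% of the published mean.

The SES gradient is not published (only the SES-specific *percent*
reductions are). The default factors (low 1.08 > medium 1.00 > high 0.92)
preserve the overall mean and give an effective population-wide reduction
of 6.84% under the average 10%-tax scenario, close to the ~6.7% implied by
the published per-capita reductions; the gradient is an explicit
configuration knob, not an estimate. The age gradient (1.25/0.8725/0.60)
mirrors the published pattern of younger adults dominating the top
consumption quartile; it too preserves the overall mean.

### What the generator does not emulate

Complex survey design (strata, PSUs, replicate weights), item-level
food-frequency data, correlation between consumption and BMI within
strata, secular consumption trends, and any correlation between expansion
weights and covariates. Tests that pass on this population demonstrate
the *pipeline's* correctness and calibration; they do not validate the
published point estimates on real microdata.

## Tax scenarios

Four immutable scenarios map SES tertile to a fractional purchase
reduction: `avg10` (9.1/5.6/5.5%), `peak10` (17.4/13.1/6.8%), and `avg20`
/ `peak20` with exactly doubled fractions (a registry assertion enforces
the doubling). The reduction is applied to each individual's consumption
as a permanent step at `t = 0` — no phase-in, no erosion. Volume converts
to energy at 0.388 kcal/ml, the ratio of the published baseline energy and
volume means; to servings at 355 ml (one can). Both constants are
configurable: the energy density of an actual beverage basket, and the
serving size the diabetes relative risk refers to, are genuinely
uncertain, and the serving definition was left unstated in the source
meta-analysis. A caloric-substitution knob exists (default 0: the base
case assumes substitution toward non-caloric drinks).

## The weight-change model

For each individual we integrate fat mass `F`, lean tissue `L`, glycogen
`G` and extracellular fluid `ECF` (kg), with body weight
`BW = F + L + G(1 + 2.7) + ECF`:

* energy balance `ρ_F dF + ρ_L dL + ρ_G dG = I − E`;
* Forbes partition: the share of the tissue imbalance routed to lean mass
  is `p(F) = C/(C+F)` with `C = 10.4 ρ_L/ρ_F ≈ 2 kg`, so that
  `dL/dF = 10.4/F`, the classic lean-vs-log-fat relationship;
* expenditure
  `E = K + γ_F F + γ_L L + δ·BW + f_TEF·I + β_AT·ΔI + η_F dF/dt + η_L dL/dt`;
* glycogen tracks carbohydrate intake, `dG = (CI − CI₀(G/G₀)²)/ρ_G`, and
  ECF relaxes toward a carbohydrate-dependent offset — both matter only
  in the first weeks and are negligible at the 10-year horizon reported.

Parameter defaults are the standard Hall-literature values
(`ρ_F` 9441, `ρ_L` 1816, `ρ_G` 4180 kcal/kg; `γ_F` 3.2, `γ_L` 22
kcal/kg/day; `η_F` 180, `η_L` 230 kcal/kg; `β_AT` 0.14; `f_TEF` 0.10;
`G₀` 0.5 kg with 2.7 kg water/kg). They are shipped as defaults of
`hall_parameters()`, versioned with the package, and are documented as
literature values rather than values asserted by any single study.

**Initialization.** Fat mass comes from the Deurenberg (1991) regression
`%fat = 1.20·BMI + 0.23·age − 10.8·male − 5.4` (sex-specific: women carry
more fat at equal BMI); ECF starts at 22% of body weight and lean tissue
closes the sum to measured weight. Compositions outside the physiologic
range raise an error naming the individual — they are never silently
clamped. Resting metabolic rate uses Mifflin–St Jeor; baseline intake is
`I₀ = PAL · RMR` with PAL 1.5 for everyone (the sedentary assumption),
and the activity coefficient `δ` and offset `K` are solved so expenditure
exactly equals `I₀` at `t = 0` — an unperturbed individual holds constant
weight by construction. Individuals with chronic disease are simulated
identically; disease-specific weight trajectories are out of scope.

**Numerics.** A fixed-step RK4 integrator (default `dt` = 1 day) runs all
individuals simultaneously as one vectorised system. Verification, all in
the test suite: zero-perturbation drift < 0.01 kg over 10 years; 10-year
weights within 0.1% of a forward-Euler integration at `dt` = 0.01 day and
within 10⁻⁴ of `deSolve::lsoda` at `rtol` 10⁻¹⁰; `dt` = 1 vs 0.1 day
differ by < 0.01%. A closed-form steady state (root of the algebraic
balance along the Forbes curve) provides the `t → ∞` oracle; the
steady-state response for reference adults is 0.040–0.053 kg per kcal/day
— bracketing the familiar ~24 kcal/day-per-kg rule — and rises to
~0.059 for obese women, slightly above the classic band, because their
weight change is almost entirely low-cost fat tissue.

A 10% average-effect tax removes ~8.4 kcal/day on average; with a ~470-day
time constant the 10-year response is essentially the steady state, giving
a mean BMI reduction of ~0.16 kg/m² (avg10), ~0.33 (avg20) and ~0.30
(peak10) on the default population — near-linear in the shock, which is
why the 20% tax roughly doubles every effect.

## BMI outcomes

WHO categories with lower-inclusive boundaries (25.0 → overweight,
30.0 → obese). Prevalence tables are survey-weighted and report relative
percent change against baseline, matching the published "(% change)"
convention; only endpoint classification is reported (category crossings
mid-horizon are not tracked). Age groups are fixed at 20–39/40–59/60+.
Empty strata report `NA`, never zero. All tables are invariant to
rescaling the expansion weights by a constant.

## The diabetes projection

A deterministic multi-cohort Markov model advances counts on an age
(0–100, open top bin) × sex × SES grid through states *no diagnosed
diabetes → diagnosed diabetes → dead*, in annual cycles from 2015 to
2050. Rates convert to probabilities as `1 − exp(−rate)` per cycle; no
half-cycle correction (available as a modelling refinement but off by
default, matching the plain annual-cycle convention).

Synthetic demographic inputs (the real analysis uses national vital
statistics and population projections):

* **incidence**: logistic in age, zero before 20, plateau `rate_max` ·
  scenario multiplier (optimistic 0.75, intermediate 1.00, pessimistic
  1.30), default `rate_max` 0.020/yr, midpoint 50 y, slope 0.08/yr;
* **mortality**: Gompertz per sex (levels 7·10⁻⁵/5·10⁻⁵, slope 0.085/yr);
* **births**: 2.2 M/yr, 51.2% male; **initial pyramid**: 121 M with
  exp(−0.015·age) shape.

Start-year prevalence is seeded by running a single-cohort recursion at
half the scenario incidence — representing the recent surge in diagnosed
diabetes (historical incidence below projected) — which produces a rising
adult prevalence: ~11% in 2015 to ~14.4% in 2050 under the intermediate
scenario, inside the published 13.6–22.5% envelope for 2050. These
constants were fixed once, from that envelope and the published secular
pattern, before any downstream results were inspected.

The tax enters as an SES-specific incidence multiplier
`RR^Δservings` with RR 1.26 per daily serving (CI bounds 1.12/1.41
available), applied on the hazard scale — the standard choice; applying
it to the annual probability instead would differ only in the third
decimal at these rates — where `Δservings` is the SES-group
survey-weighted per-capita mean change. It applies from the first
projected year (step change). Averted cases are cumulative baseline-minus-
counterfactual incident cases. Diabetic excess mortality is a
configurable hazard ratio, default 1.0, since the source treatment of
excess mortality is not published; raising it lowers observed prevalence,
so the published 2050 envelope is used as a calibration band, not a point
target. Conservation (launched persons + births = alive + dead, per
cohort) holds to floating-point accuracy and is asserted in tests.

## CRA sensitivity analysis

The comparative-risk-assessment route bypasses the ODE:
`ΔBMI = β · Δservings`, time-independent, with β from meta-analyses:
pooled experimental 0.85 and observational 0.22 kg/m² per serving/day,
and single-study extremes 0.11, 1.09 and 2.12. Applied unweighted,
cross-sectionally, against baseline weight.

Worth stating plainly: at a 10-year horizon the energy-balance model
implies ≈ 2.6 kg/m² per sustained daily serving (one 355-ml can ≈ 138
kcal/day ≈ 0.65 kg/m² at steady state for a 1.65-m adult), *larger than
every listed coefficient*, so under the time-independent reading the ODE
population mean is the most negative entry of the comparison table. If
the coefficients are instead read as annual rates accumulated over the
horizon — the reading consistent with describing them as limits on
*annual* weight change — the ODE mean falls between the pooled
observational and experimental brackets. The package implements the
time-independent contract and the test suite pins down both relationships.

## Problem sizes and determinism

Default study conditions: n = 10,000 individuals, 10-year integration at
`dt` = 1 day (~13 s per scenario), 2015–2050 projection (< 1 s). The
test suite uses n up to 50,000 for marginal-recovery checks and 5·10⁵
replicate microsimulations for the Markov oracle. Every stochastic
component draws from an explicit seed; `run_pipeline()` fans one root
seed out to stage seeds and records a manifest, and identical
configuration yields byte-identical outputs.

## Known limitations

* Synthetic marginals, not microdata: stratum-level results (e.g.
  quartile-specific obesity changes) are structurally faithful but not
  numerically comparable to the published stratified tables.
* The ZILN consumption model cannot hold the published mean, SD and
  quartiles simultaneously (above); the SD is deliberately sacrificed.
* No caloric substitution by default; no children; no undiagnosed
  diabetes; no cardiovascular outcomes; no cost analysis.
* The diabetes model's demographic inputs are stylised (constant births,
  Gompertz mortality); prevalence *levels* are calibration, only the
  tax-attributable *differences* between arms are interpretable.
* Purchase-to-consumption pass-through is taken as given from the demand
  study; elasticities are out of scope.
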