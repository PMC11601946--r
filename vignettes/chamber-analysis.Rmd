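---
title: "Methods: chamber calorimetry and the crossover metabolome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber calorimetry and the crossover metabolome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chamberomics implements the analysis chain of a controlled-feeding,
crossover metabolic-chamber study: indirect calorimetry, metabolomics QC,
diet-effect models, and metabolite–physiology association models, together
with a synthetic cohort generator that stands in for clinical data held
under controlled access. This vignette documents the models, the tunable
parameters, and the design decisions taken where the methodology left
genuine latitude.

```{r setup}
library(chamberomics)
```

## Indirect calorimetry

Chamber air is sampled each minute, giving per-minute oxygen consumption
VO2 and carbon dioxide production VCO2 (L/min). The respiratory quotient is
RQ = VCO2/VO2, and per-minute energy expenditure uses the caloric
equivalent of oxygen:

$$\mathrm{EE} = \dot{V}O_2 \times \left[4.686 + (\mathrm{RQ} - 0.707)
\times \tfrac{0.361}{0.293}\right] \quad \text{kcal/min}.$$

The bracketed term is a kcal-per-liter-O2 factor: 4.686 kcal/L at the fat
RQ of 0.707, rising linearly to 5.047 kcal/L at RQ 1. A formula of this
shape admits a second reading in which only the constant term is scaled by
VO2; we scale the whole bracket, the standard caloric-equivalent
interpretation, and note that the two coincide at VO2 = 1 L/min — which is
how the printed-constant checks in the test suite are framed.

Daily totals extrapolate the per-minute values by 1,440. The 24-hour RQ is
the **ratio of total VCO2 to total VO2** over retained minutes, not the
mean of per-minute ratios; with near-complete traces the two differ only in
the fourth decimal, but the ratio-of-totals is the quantity that enters the
substrate equations, so it is the one reported.

**Minute-gap policy.** Real chamber traces drop minutes. Gaps of at most 5
consecutive minutes are filled by linear interpolation; a session with a
longer gap, or with less than 95% of its 1,440 minutes, is rejected rather
than patched. The thresholds are `max_gap` and `min_coverage` arguments of
`aggregate_24h()`.

**Substrate oxidation.** Protein oxidation is 6.25 g per g of 24-hour
urinary nitrogen, at 4.70 kcal/g. Carbohydrate and fat follow the Frayn
stoichiometric inversion (volumes L/day, nitrogen g/day):

$$\mathrm{CARBOX} = 4.55\,VCO_2 - 3.21\,VO_2 - 2.87\,N, \qquad
\mathrm{LIPOX} = 1.67\,(VO_2 - VCO_2) - 1.92\,N,$$

with per-gram gas volumes of 0.746/0.746 (glucose), 2.019/1.427 (fat) and
0.966/0.782 (protein) L O2/L CO2, and energy densities 3.74/9.46/4.70
kcal/g (`fuel_stoichiometry()`). These constants are internally consistent:
a day synthesized forward from known substrate masses is inverted back
within about 1–2% of total mass (the residual is rounding of the published
coefficients), and substrate energy closes on Lusk EE within 2–3%
(`energy_closure()`). The nonprotein RQ removes protein-attributed gas
exchange before taking the ratio; values outside (0.69, 1.05) — beyond the
pure-fuel RQ range with margin — are **flagged, never dropped**, as are
negative oxidation estimates at extreme RQ, so downstream models can
exclude them explicitly rather than inherit silent clipping.

## Protocol encoding

The diet library holds the seven chamber conditions: energy balance (EB),
24-hour fasting, and five overfeeding diets at 200% of the individual's
energy needs — standard (SOF), low-protein (LPF, 3% of energy from
protein), high-fat/normal-protein (FNP), high-fat/high-protein (HPF), and
high-carbohydrate (CNP). The macronutrient fractions shipped as defaults
(EB/SOF 50/30/20 C/F/P, LPF 51/46/3, FNP 20/60/20, HPF 25/45/30, CNP
75/5/20) are **synthetic placeholders** with the right qualitative
structure; studies with their own prescriptions supply them via
`diet_library(overrides=)` or a YAML file (`read_diet_library()`).

A participant's sequence is: a first eucaloric chamber whose measured
24-hour EE calibrates the energy-balance prescription; the EB chamber; then
the six interventions in a seeded Fisher–Yates random order with a washout
(3 days in the simulator; the protocol minimum) before each. The
calibration session is not an analysis chamber: schedules carry it with
`chamber_order = NA`, and the seven monitored diet conditions are ordered
1 (EB, first for every participant) through 7. Model code treats chamber
order numerically by default; a categorical coding is available, and the
two agree when carry-over is absent.

Eligibility applies the oral-glucose-tolerance thresholds (impaired
regulation at fasting ≥ 100 mg/dL or 2-h ≥ 140 mg/dL; diabetes at ≥ 126 or
≥ 200), and compliance withdraws any fed session at or below 95% of
provided energy consumed. Whether the original accounting was by energy or
food mass is not stated in the protocol source; we use energy, which is the
quantity the schedule prescribes.

## Metabolite QC

The pipeline order is fixed and idempotent:

1. **Outlier review** of *prechamber* levels within each (diet, metabolite)
   group: values beyond 5 SD of the group mean are set to missing. The SD
   includes the candidate value (a leave-one-out rule was not specified);
   with the candidate included an observation k clean-SDs out scores
   $z = k/\sqrt{1 + k^2/n}$, so the effective bar is somewhat above 5 clean
   SDs — an 8-SD injection in a group of 50 still trips it. Groups smaller
   than 3 are never trimmed (the SD is too unstable to judge). Postchamber
   values are not screened, matching the stated procedure.
2. **Missingness exclusion**: any metabolite with any missing value —
   including those created by outlier removal — is excluded outright.
   Nothing is imputed.
3. **log2 transform**: fold change = log2(post) − log2(pre) per session and
   metabolite, with log2(pre) retained as the baseline covariate. Log base
   2 is used everywhere so coefficients read per doubling.

Pooled-QC CVs are computed on raw abundances (100·SD/mean per metabolite)
with the median and IQR summarized across the panel.

## Statistical models

**Per-chamber tests.** For each diet, a two-tailed paired t test per
metabolite on log2 levels (identically: mean log2FC against zero), with BH
q-values computed within that chamber's metabolite family only — families
are never pooled across diets. Metabolites with fewer than 3 pairs or zero
variance are flagged and withheld from the family. The implementation is a
vectorized t statistic cross-checked in the tests against `t.test()` and a
brute-force BH step-up oracle, and its empirical FDR under a mixed
null/effect simulation is verified ≤ 7% at q < 0.05.

**Crossover diet effects.** Per metabolite:
`post_log2 ~ pre_log2 + diet + chamber_order + (1 | participant)`, EB
referent, REML via lme4 with Satterthwaite p-values via lmerTest. Only a
random intercept is used (no slopes were specified by the design). Fits
with a zero participant-variance estimate are flagged `singular` and kept —
their fixed effects equal OLS exactly, which doubles as an oracle test —
and non-convergence yields a `failed` row, never a silent drop.

**Physiology associations.** Per metabolite and outcome (24-h EE, RQ,
LIPOX, CARBOX, PROTOX):
`outcome ~ log2FC + pre_log2 + diet + age + sex + race + BMI + (1 | participant)`,
with per-diet stratified ordinary least squares as a sensitivity analysis
(refusing duplicated or underdetermined designs), and the NEFA variant
adding prechamber NEFA as a covariate. Both the fold-change and the
baseline-level coefficients are reported; their Spearman correlation across
metabolites (`baseline_change_concordance()`) summarizes whether baseline
abundance and in-chamber excursion carry the same signal. Covariates enter
unstandardized so betas are per doubling; race is an unordered categorical.
Whether the original analysis FDR-corrected these models is unstated, so BH
per outcome family is computed but toggleable (`adjust = FALSE`).

## The synthetic cohort

`simulate_cohort()` generates, under a single seed: participants (~20%
female, ages around 38, BMI around 26, weight series with ~0.9% CV, and an
allometric energy need 70·kg^0.75 kcal/day — chosen for relative structure,
not as a published predictive equation); schedules; minute traces; panels;
and NEFA. Everything is deterministic given the seed and the ground truth
is returned alongside.

Traces are built by **forward stoichiometry**: a daily oxidized-energy
budget (EB need scaled by a per-diet response — fasting 0.92, overfeeding
1.06–1.15 with the high-carbohydrate diet highest, reflecting
carbohydrate's larger thermic effect) is spread over the day by a diurnal
profile (sleep dip 23:00–06:30 at 82%, post-meal thermogenesis bumps after
the 11:00/16:00/19:00 meals), split into fuel by an oxidized mix, and
converted to VO2/VCO2 per gram. The oxidized mix blends the prescribed
macronutrient split with a 50/30/20 endogenous baseline at weight 0.4 —
oxidation tracks intake only partially within a single day because
endogenous stores buffer it — and the fasting day drifts linearly from
50/30/20 toward 15/70/15 as lipolysis ramps up. Multiplicative AR(1) noise
(stationary SD 2%, coefficient 0.9) models analyzer drift and short-scale
physiology. Urinary nitrogen is oxidized protein / 6.25, so the calorimetry
engine applied to a noise-free trace recovers the true masses within the
coefficient-rounding tolerance.

The metabolome follows the crossover model it is meant to exercise:
log-normal prechamber abundances; postchamber log2 level = prechamber +
diet-by-class effect + participant intercept (SD 0.15) + residual (SD 0.2).
The default effect matrix (`default_effect_matrix()`) encodes the expected
sign structure — acylcarnitines up under fasting and high-fat overfeeding,
down under high-carbohydrate; glycerophospholipids opposite; amino acids
down in fasting except branched-chain amino acids up — which makes the
fasting and high-carbohydrate response patterns strongly inverse and the
low-protein chamber the least concordant. Two couplings tie the metabolome
to physiology: a **session-level fat shift** (SD 0.08 energy fraction,
partly driven by a participant-level latent lipid-oxidation propensity)
moves both the oxidized mix and, through per-class coefficients
(acylcarnitines +4, glycerophospholipids −3 log2 per unit shift), the
metabolite excursions; and the same propensity shifts prechamber levels
(+0.25 log2/SD for acylcarnitines), which is what makes baseline and
fold-change betas concordant. NEFA is prechamber ~0.5 mEq/L plus 0.15 mEq/L
per SD of LIPOX. Pooled-QC replicates (8 per metabolite) target a 5% CV and
5% of metabolites receive injected missing values to exercise the exclusion
rule.

**What the generator does not emulate** — and therefore what passing tests
do and do not show: there is no insulin or other hormonal dynamics, no
adaptive thermogenesis beyond the static per-diet response, no
food-specific or microbial metabolites, no batch structure or
intensity-dependent missingness in the panel, and within-class effect
heterogeneity is a single residual SD (the source analyses do not quantify
it, so the defaults are declared rather than inferred). Green tests
demonstrate that the estimators are correct and calibrated under the
assumed generating model, not that real chamber data satisfy that model.

## Numerical choices and problem sizes

Degenerate inputs are rejected early (nonpositive VO2, negative nitrogen,
single-weight CVs) or flagged (out-of-range nonprotein RQ, negative
oxidation, zero-variance metabolites). Interpolation at trace edges extends
the nearest observed value. Tests freeze hand-computed expected values and
compare model routes against independent oracles (direct t tests,
brute-force BH, OLS-equivalence at the variance boundary).

The shipped simulations use 50 participants × 60 metabolites for the
default cohort, 500 replicates × 200 metabolites for the FDR calibration,
and 200 replicates at n = 60 for mixed-model coverage — sizes at which the
stochastic checks are stable across seeds while the full suite runs in
about a minute.

## Known limitations

The Frayn coefficients assume glucose as the oxidized carbohydrate and a
fixed fat composition; glycogen or unusual lipid pools shift the constants
by ~1–2%. Protein oxidation from a single 24-hour urine collection ignores
nitrogen-pool kinetics. The compliance and eligibility filters implement
the stated thresholds literally (boundary values excluded at ≥, withdrawn
at ≤ 95%); studies with different conventions should filter upstream. The
per-metabolite mixed models fit independently, so cross-metabolite
correlation enters only through the BH correction.
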