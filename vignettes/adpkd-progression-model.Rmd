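---
title: "Modelling lifetime CKD progression in rapidly progressing ADPKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lifetime CKD progression in rapidly progressing ADPKD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpkdprog)
```

## The model

`adpkdprog` is an annual-cycle cohort model of chronic kidney disease (CKD)
progression in autosomal dominant polycystic kidney disease (ADPKD) patients
at risk of rapid progression — Mayo imaging subclasses 1C, 1D and 1E, which
correspond to estimated annual kidney growth of 3–4.5%, 4.5–6% and > 6%.
Six health states are modelled: KDIGO stages G1–G5 (G5, eGFR below
15 mL/min/1.73 m², is treated as end-stage renal disease, ESRD) and death.
Patients enter in stages G1–G3, decline in eGFR every year, are reassigned
to the stage their updated eGFR implies — never to a better stage — and die
at state- and age-specific rates. Subclass membership is fixed for life:
progression rates are stable within patients, so a 1D progressor never
becomes 1C or 1E.

The cohort is stratified rather than individual: each of the 18
sex × baseline-stage × subclass strata is a homogeneous representative
patient weighted by its count. The published cohort description provides
only stratum means, so within-stratum heterogeneity of age and eGFR is not
simulated; consequences are discussed under *Limitations*.

### eGFR decline

Future eGFR is predicted by the Irazabal equation, linear in time from
baseline with coefficients for sex, baseline age, baseline eGFR, and
subclass. Writing `t` for years from baseline, the trajectory used by the
engine is

```
eGFR(t) = anchor + (epsilon + lambda * I_sex + mu * age0 + sigma_k) * t   [+ mu * t^2]
```

Three aspects of the published equation text are under-determined, and each
is an explicit, switchable convention (`equation_modes()`):

* **Sex indicator** — the equation text reads "(1 if male)" for the
  sex × time term while the coefficient table marks male as the reference
  level for both sex terms. Default: female indicator for both terms (the
  consistent table reading, which also gives males the faster decline, in
  line with ADPKD epidemiology). `male_indicator` retains the literal text.
* **Age interaction** — the coefficient table labels the μ × time term with
  *baseline* age (linear trajectories); the equation text prints *current*
  age, which adds a `mu * t^2` term (an extra −0.02 per year², i.e. decline
  accelerating by 0.04 mL/min/1.73 m² per year each year). Default:
  `baseline_age`; the acceptance analysis runs both.
* **Anchoring** — the treatment effect is described as applied to predicted
  decline, implying increments applied to an anchor. Default: anchor at the
  observed stratum baseline eGFR, which keeps baseline stage membership
  exact. `equation_intercept` instead starts trajectories at the equation's
  own fitted value (for the male G1 1C stratum, 104.74 vs the observed
  105.0).

Under the defaults the untreated base cohort reaches ESRD after a
count-weighted mean of 16.0 years; under the current-age reading, 14.8
years. The published headline for this cohort is 13.7 years, and the
published stage-specific treated-arm pattern (percent improvement rising
from G1 to G3) emerges in this implementation only under the current-age
reading — evidence that the original model used the literal equation text.
Both readings ship; neither is hidden behind the other.

```{r conventions}
cohort <- build_base_cohort()
for (ai in c("baseline_age", "current_age")) {
  arm <- run_arm(cohort, modes = equation_modes(age_interaction = ai),
                 horizon = 75)
  cat(ai, "->", round(arm$time_to_esrd$overall, 2), "years\n")
}
```

### Stages, crossing times, and the annual cycle

Stage thresholds are half-open with the lower bound inclusive (G1 ≥ 90,
G2 ≥ 60, G3 ≥ 30, G4 ≥ 15, G5 < 15; G3 pools G3a/G3b). Stage assignment
happens at integer years under a running-worst rule, but the reported time
to ESRD is the *continuous* crossing time of the trajectory below 15,
solved in closed form (linear, or the positive quadratic root under the
current-age reading) and exactly within the bracketing year when the
treatment schedule makes the path piecewise. eGFR is floored at zero.
Crossing times deliberately ignore mortality, so they are reproducible from
the cohort table and coefficients alone; mortality affects only occupancy
and life-years. A death-censored time-to-ESRD estimand would be smaller;
the published description does not define which estimand its headline uses,
and this package reports the mortality-free one.

When a trajectory touches eGFR = 15 exactly at an integer year the closed
form counts that instant as reaching ESRD while the stage classifier maps
15 to G4; the trajectory builder resolves this measure-zero boundary in
favour of the crossing time, so state-year accounting and crossing times
always agree.

### Treatment and discontinuation

Treatment reduces the annual decline by a constant `annual_effect`
(default 1.20 mL/min/1.73 m² per year), uniformly across stages and
subclasses. Discontinuation is annual: probabilities for treatment years
1–3, year 4 assumed equal to year 3, and after year 4 only at ESRD (the
effect stops with the drug). The engine applies the *expected-value*
attenuation — the reduction in cycle `t` is the effect times the fraction
still on treatment, `prod(1 - d_i)` over completed years — because a cohort
model tracks means. The reduction is clamped at the natural decline rate
(decline never becomes improvement) and zeroed once a stratum reaches ESRD.

The year-1–3 discontinuation probabilities of the underlying trial are not
published in the model description; they are a required user input
(`treatment.discontinuation_probs` in the config). The packaged template
carries clearly labelled synthetic placeholders (0.15, 0.05, 0.03),
chosen once as plausible front-loaded trial attrition, and every packaged
test uses them as synthetic values — treated-arm magnitudes should be
interpreted accordingly until real rates are supplied.

Because stage occupancy is a threshold functional of eGFR, the
expected-effect cohort model is not identical to individually sampling each
patient's discontinuation year: by convexity of the crossing time in the
reduction, sampled-discontinuation cohorts reach ESRD slightly *later* on
average. `simulate_patients(..., sample_discontinuation = TRUE)` quantifies
this gap; the test suite asserts its direction, and asserts exact (3
Monte-Carlo-SE) agreement of cohort and patient-level accounting in the
regimes where the two estimands coincide (no treatment, or full
persistence).

### Mortality

Death probabilities are `min(1, qx(floor(age)) * RR(state))`, with `qx`
from a period life table (CSV, optionally sex-specific; the packaged
fixture is a Gompertz–Makeham table, `qx = a + c·exp(b·age)` with
a = 2e-4, b = 0.095, c = 3e-5, terminal age 100 forced to `qx = 1` — adult
mortality of a realistic contemporary magnitude, e.g. `qx(40) ≈ 0.0015`).
The risk ratios are derived from registry all-cause mortality in patients
aged ≥ 65–66 and applied at all ages, as in the source model — a documented
proxy. ESRD mortality blends the no-RRT, dialysis and transplant ratios
with an assumed substate mix (default 5% / 70% / 25%; no published split
exists), and the blend is checked at construction so a mix light enough to
break monotonicity of death risk in stage severity triggers a warning.

Within a cycle the order is: accrue one state-year for the state occupied
at cycle start, update eGFR and stage, then apply death using the age at
cycle start and the updated stage. With all risk ratios at 1 and a
non-progressing cohort this reproduces the life table's own life
expectancy exactly (the suite asserts agreement to 1e-6), which is why no
half-cycle correction is applied.

### Probabilistic sensitivity analysis

The published analysis reports a 5000-draw percentile interval but names
neither the sampled parameters nor their distributions. `run_psa()`
therefore takes an explicit parameter set; the default samples only the
treatment effect, Normal(1.20, user-supplied SD) truncated at zero via the
inverse-CDF (keeping draws exact and seed-deterministic). Equation
coefficients and risk ratios can be added as normal, lognormal or beta
draws. All randomness flows from one explicit integer seed; identical seeds
give bitwise-identical results.

```{r psa}
psa <- run_psa(psa_config(n_iterations = 200, seed = 1,
                          sd_annual_effect = 0.15),
               cohort, treatment = treatment_spec(1.2, c(0.15, 0.05, 0.03)),
               horizon = 75)
psa
```

## Numerical and design choices

* **Horizon**: 75 annual cycles by default — with baseline ages ≥ 26 and a
  life-table terminal age of 100, every stratum is extinct before the
  horizon; the engine warns if truncation ever occurs.
* **Problem sizes**: the packaged tests use the full 18-stratum cohort for
  deterministic checks, 25,000–50,000 patients for the Monte-Carlo oracle
  (3-SE agreement), and 200–10,000 PSA draws for the self-consistency
  check; a full deterministic two-arm run takes about a second and 5000 PSA
  draws about a minute on one core.
* **Ties and boundaries**: stage thresholds lower-inclusive; ESRD crossing
  strict (`< 15`) except for the integer-touch boundary described above;
  ages floored and clamped to the life-table range; treatment reduction
  clamped at the natural decline rate with a warning.
* **Validation-style errors**: every reader (cohort CSV, life-table CSV,
  YAML config) rejects malformed input with the offending row or key path;
  unknown config keys are errors, not silently ignored.

## What the synthetic fixtures do and do not show

The Gompertz–Makeham life table reproduces the *shape* of general-population
mortality, not any specific national table; life-year totals therefore
depend on the fixture and should be recomputed with a real life-table CSV
for substantive use. The synthetic cohort generator produces valid strata
with arbitrary (seeded) compositions for property testing; it does not
emulate the joint age–eGFR–subclass distribution of a real trial
population. Passing tests demonstrate internal correctness of the equation,
engine accounting, and treatment/mortality machinery — not calibration of
discontinuation, ESRD substate mix, or mortality to any particular
population.

## Limitations

* Stratum means instead of patient-level heterogeneity: crossing times are
  those of mean trajectories, which convexity makes earlier than the mean
  of heterogeneous crossing times.
* The equation-reading ambiguities shift the untreated headline by about
  1.2 years and change the stage pattern of percent improvement; both
  readings are shipped, and results should state the conventions in force
  (the JSON summary records them).
* Constant lifetime treatment effect; no titration, adverse events, or
  stage-specific effects. Discontinuation rates are user inputs.
* ESRD substates exist only as a mortality blend — no dialysis/transplant
  transition dynamics.
* No discounting, costs, or quality-of-life weighting: outputs are natural
  units (years, life-years, state shares).
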