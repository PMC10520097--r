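---
title: "Modelling the global burden of type 1 diabetes with a Markov cohort engine"
author: "t1dsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the global burden of type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dsim)
```

## The model

Type 1 diabetes (T1D) burden estimation faces a data problem: most countries
have no published incidence series, mortality in people living with T1D is
rarely observed directly, and in low-income settings a substantial share of
onsets die undiagnosed and never appear in any registry. `t1dsim` addresses
this with a deterministic annual-step Markov cohort model. One birth cohort
per calendar year is followed from age 0 to a terminal age $A_{\max}$
(default 99, absorbing) through five states: alive without T1D, alive with
diagnosed T1D (sub-indexed by age at diagnosis, so disease duration is always
recoverable), dead at onset from non-diagnosis, dead after diagnosis, and
dead from background causes.

Within each model year events happen in a fixed order:

1. onset of symptomatic T1D among the susceptible, at the incidence rate
   $i(a, y) / 10^5$;
2. a fraction $d(a, y)$ of the new onsets — the non-diagnosis rate — dies
   immediately, undiagnosed;
3. background death among the remaining susceptible with probability
   $q(a, y)$;
4. death among all diagnosed (including this year's onsets) with probability
   $q_{T1D} = 1 - (1 - q)^{\mathrm{SMR}(a, y)}$.

The ordering is a modelling choice the underlying evidence does not pin
down; placing the non-diagnosis deaths directly after onset matches the
survey definition of dying "soon after onset", and exposing this year's
survivors of onset to diagnosed mortality in the same year keeps every person
accounted for in exactly one state (cohort conservation is asserted at
every step to a relative $10^{-9}$). The standardised mortality ratio (SMR)
is applied on the hazard scale rather than as a direct multiplier
$q \times \mathrm{SMR}$, which would exceed 1 at old ages; the two agree to
first order when $q$ is small.

Aggregating cohorts gives diagnosed prevalence, incident diagnosed cases and
deaths decomposed into the three channels, per age and year. Two derived
quantities matter downstream:

* **Life expectancy at onset** — expected remaining years for a person
  developing symptomatic T1D at a given age and year, with the onset
  non-diagnosis risk included and deaths credited half a cycle (0.5 years)
  in the year they occur. Beyond the data horizon, surfaces are extended by
  last-value carry-forward — recent-onset cohorts need rates decades into
  the future, and holding the last observed year constant is the most
  conservative defensible extension.
* **Missing prevalence** — the counterfactual minus factual diagnosed
  prevalence in a year, where the counterfactual sets the non-diagnosis rate
  to 0 and the SMR to 1 with all else equal. It is the number of people who
  would be alive with T1D under perfect diagnosis and no excess mortality.

## Input construction

**Incidence.** Observed incidence series are sparse, so complete
age-by-year surfaces are built in three steps. Series are smoothed with a
centred moving average (default window 5 years, truncated at the series
edges). Year-on-year annual percentage changes (APC) are pooled across
countries — keeping years in the 1985–2015 support where at least two
countries contribute — and an ordinary least-squares line of change against
year is fitted, globally and per region (regions failing the two-country
rule fall back to the global curve). Levels are then extrapolated by
compounding the curve from an anchor observation; incidence before 1975 is
held constant at the 1975 value, since almost no data exist before then (a
linear-decay or zero-ramp alternative could be substituted, but the constant
floor is the default and the one the tests pin). Countries with no data at
all get the median donor series of their region-and-income stratum
(widening to region, then global), scaled by a log-linear regression of
incidence on income group and region; the regression form is a replaceable
design decision.

The age shape of incidence comes from a modelled onset-age density: a
childhood bump with its mode in the 10–14 band mixed with a broad adult
component carrying the majority of the mass (median onset in the late
twenties), because adult-onset T1D is more common than childhood onset even
though the incidence *rate* peaks in early adolescence. A separate variant
with a later childhood peak is used for sub-Saharan Africa. The density is
rescaled so its population-weighted mean under a reference age structure is
1, making each year's column integrate back to the all-age level.

**Mortality.** Two ingredients. Non-diagnosis death rates come from a
survey-based schedule by region and era (before 2000, 2000–2010 closed,
after 2010), structurally zero at ages 25 and over and in high-income
countries. Only the Sub-Saharan-Africa pre-2010 cell (60%) of the packaged
schedule is an externally reported value; the other cells are synthetic
placeholders, chosen once for plausibility, and the packaged file is named
`nondx_survey_synthetic.csv` to say so. SMRs for people living with
diagnosed T1D are predicted from country covariates (infant mortality,
doctors per capita, GDP per capita, under-5 mortality, urbanisation, year,
region, income class). The default learner is distance-weighted
k-nearest-neighbours on standardised covariates: transparent, exactly
interpolating at its support points, and trivially deterministic. A linear
least-squares learner sits behind the same interface; it is the right tool
when the target relationship is itself linear, and it is what the
predictor-recovery experiment uses, since k-nearest-neighbour averaging
cannot reach the experiment's error bound in a six-dimensional covariate
space from a couple of hundred points. Predictions are clipped to
$[1, \mathrm{max\_smr}]$: an SMR below 1 for T1D is implausible. The age
pattern of SMR is assumed constant across countries and years; the packaged
default shape is flat, which is an explicit placeholder rather than an
estimate. A monotone knot table maps mean HbA1c to SMR by piecewise-linear
interpolation, connecting care levels (minimal ≈ 12% HbA1c, intermediate ≈
9%, best ≈ 7%) to mortality.

**Diagnosis-rate inference.** Where observed incidence rises much faster
than true incidence plausibly can, the ratio of observed incidences equals
the ratio of true incidences times the ratio of diagnosis rates. The package
decomposes an observed ratio accordingly and bounds the baseline diagnosis
rate. The printed worked example (incidence 0.12 → 0.74 per 100,000 over
2007–2016) reproduces with an elapsed time of 9 years; the unrounded chain
is computed first and each reported step is rounded to one decimal (the
baseline rate to a whole percent), which is the convention that matches the
published figures.

## Healthy life years

HALYs lost at onset are computed in two stages. A care level fixes a mean
HbA1c, hence an SMR, hence the survival of a person diagnosed at
$(a_0, y_0)$. Eight complications (distal symmetric polyneuropathy, ulcer
or amputation, hypertension or microalbuminuria, overt nephropathy,
proliferative retinopathy, blindness, non-fatal myocardial infarction,
non-fatal cerebrovascular disease) then occur de novo each year,
conditionally independently given glycaemic control, with an annual hazard
$\mathrm{logit}^{-1}(\beta_0 + \beta_1 \cdot \mathrm{HbA1c} + \beta_2
\cdot \mathrm{duration})$; acquired complications persist. Two
"impermissible journeys" are disallowed: de-novo proliferative retinopathy
in an already blind individual, and de-novo hypertension/microalbuminuria
given overt nephropathy. The joint distribution over the $2^8 = 256$
complication states is propagated exactly (one vectorised pass per
complication per year, ordered so a blocked complication's pass always reads
the blocker's start-of-year state; the tests verify this equals exhaustive
path enumeration to $10^{-12}$). Hazard coefficients and disability weights
are configuration inputs with plausible defaults — the source cohort's
fitted equations are not public, so the defaults are placeholders with the
right qualitative behaviour, and beyond the 30-year evidence horizon the
duration-30 hazard is held constant (zeroing it is available as an
alternative).

HALYs lost split into a death component (background remaining life
expectancy minus model life expectancy at onset) and a disability component
(each survived person-year weighted by the expected disability of the joint
complication state, combined multiplicatively across coexisting
complications as $1 - \prod_c (1 - w_c)$; additive-capped is available).

## Projections

Two scenarios: *conservative* holds incidence, SMR and non-diagnosis rates
constant at their last data-year values; *momentum* compounds each forward
at its per-age geometric mean annual ratio over 2012–2021 (geometric, so the
compounding is self-consistent; the non-diagnosis rate trends through its
complement $1 - d$ so projected values stay in $[0, 1]$). Future population
must be supplied, or is carried forward constant with a warning.

## The synthetic data generator

Nothing in the package depends on external data. `make_country()` builds
complete, internally consistent bundles for five archetypes —
HIC-high-incidence, HIC-low-incidence, UMIC, LMIC, LIC-SSA — whose
parameters were chosen once to bracket the observed global spread:
childhood prevalence in real countries spans roughly 1.5 to 534 per
100,000, incidence from a fraction of 1 to over 50 per 100,000, SMRs from
near 1 in the best-resourced settings to around 10 in the poorest, and
non-diagnosis rates up to 60%. Background mortality is a Siler-style curve
(infant hump, adult plateau, Gompertz old-age rise) improving slowly
through time; births grow at an archetype rate; incidence uses the
archetype's onset variant and APC. What the generator does *not* emulate:
migration, period shocks (wars, pandemics), registry noise and
misclassification, and within-country heterogeneity — so passing tests
demonstrate the machinery is correct under clean inputs, not that any real
country's estimates are reproduced. `make_smr_training()` samples country
covariates along a latent development gradient (so they co-vary the way
real country statistics do) and attaches its generating function, making
predictor-recovery experiments self-checking. At default settings the
generator is deterministic; the seed matters only when observation noise is
switched on.

## Numerical choices and scales

Cohort conservation is enforced at every step to a relative $10^{-9}$.
Rounded percentage pairs adjust the larger share so the pair always sums to
100. The engine's default problem size — 100 ages by roughly 110 years, one
cohort per birth year — runs a country in well under a second, and the
package's test suite uses microsimulation oracles of $10^5$–$10^6$
individuals and exhaustive path enumeration on small complication registries
as its independent cross-checks; these sizes give 3-standard-error bands
tight enough to catch order-of-operations mistakes while keeping the suite
quick.

## Known limitations

The packaged non-diagnosis schedule, HbA1c–SMR knots, complication hazard
coefficients and disability weights are configuration defaults, not fitted
values. The SMR age shape is flat. Uncertainty intervals are out of scope —
the engine is deterministic and reports point estimates. Sub-national
variation and migration are not modelled. Real-country calibration requires
assembling the real input surfaces, which this package deliberately does
not ship.
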