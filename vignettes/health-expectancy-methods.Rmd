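---
title: "Methods: Sullivan health expectancy for registry survivor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sullivan health expectancy for registry survivor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthexp)
```

## The estimand and the data it needs

The package estimates, for a cohort of cancer survivors observed over a
calendar window, the expected remaining years of life at chosen ages and how
those years divide between health states. Two states are supported: good
versus poor self-rated health (SF-36 general-health item, dichotomized as
excellent/very good/good against fair/poor) and free versus not free of
walking limitation (SF-36 walking item, with "very much" and "a little bit"
limited both counting as limited). The corresponding expectancies are the
healthy life expectancy (HLE) and the disability-free life expectancy (DFLE).

Two inputs drive everything: person-level registry survival records and a
cross-sectional survey of a subsample. The method is the classical Sullivan
construction: a period life table from the registry, age-specific prevalence
from the survey, and person-years weighted by the probability of being in
the favourable state.

Its key assumption is worth stating plainly: the cross-sectional prevalence
of each age group is treated as the fraction of that age group's life-table
person-years spent in the adverse state. This is a stationarity assumption —
it ignores health dynamics within age groups and any cohort trends in
prevalence. It is the standard trade-off when longitudinal transition data
are unavailable; an incidence-based multistate model is out of scope here.

## Cohort selection and person-time

A survivor enters the analysis if, inside the observation window, there is
an instant at which they are alive, already diagnosed, and at or above the
minimum age (default 50 years). Exposure runs from
`max(window start, diagnosis, 50th birthday)` to `min(exit, window end)` and
is cut at exact birthday instants into half-open age intervals
`[lower, upper)`; the default grid is 50, 55, ..., 85 with an open 85+ group.
Ages are exact real-valued year fractions on a 365.2425-day year, so a
person contributes to 65–69 from the very instant of the 65th birthday;
calendar dates themselves are handled at day resolution, which is why the
conservation guarantees are stated "to one day per person". The calendar
period is collapsed — one window, no age-by-period Lexis triangles — because
the analysis targets a single recent period's rates.

Two deliberately exposed choices:

* **Alive-in-window rule.** "Alive between the window years" is read as
  alive at *any instant* inside the window (`alive_rule = "any_instant"`);
  the stricter reading — a diagnosed, living survivor on the window's first
  day — is available as `alive_rule = "at_start"`.
* **Follow-up class.** Time since diagnosis is classed short ("5 years or
  less", boundary included) versus long at the person's *entry* into the
  window, and frozen there. A dynamic alternative — a person graduating from
  short to long mid-window, which would add another cut to the person-time
  splitter — is a known limitation, not implemented, because the frozen
  classification is the one the stratified tables use.

## The abridged life table

With deaths `D_x` and person-years `P_x` per interval, `m_x = D_x/P_x`,
and the table follows the standard abridged identities (radix 100,000):
`q_x = n_x m_x / (1 + (n_x - a_x) m_x)` capped at 1, `a_x = n_x/2` for closed
intervals, and the open interval closed exponentially by `q = 1`,
`L = l/m`. The midpoint `a_x` convention is the pragmatic default for a
cohort that starts at age 50; infant-mortality refinements are irrelevant
here, and `a_x` is exposed as an argument for sensitivity analyses.

Numerical edge cases are explicit rather than silent:

* `P_x = 0` with `D_x > 0` is a hard error (corrupt exposure).
* `P_x = 0` with `D_x = 0` yields `m_x = 0` under the default zero-cell rule;
  no smoothing is applied, and intervals with exposure but no deaths are
  logged. Transparency is preferred to borrowed strength; pooling adjacent
  groups is the user's decision, not a hidden default.
* A zero open-interval rate cannot close the table and raises an error
  telling the user to supply a positive terminal rate (e.g. a coarser grid).
* Very high rates can cap `q` at 1 before the last interval; survivorship
  is then extinct and later reporting ages are undefined. The stratified
  runner flags such stratum/age cells (`sparse = TRUE`, `NA` estimates)
  instead of aborting — this genuinely occurs for metastatic-stage strata at
  old reporting ages.

## Prevalence and the Sullivan combination

Respondents are indexed by age at survey (not at diagnosis), respondents
below the grid floor are excluded, and missing items leave both numerator
and denominator. Each cell carries the binomial standard error
`sqrt(pi (1 - pi) / n)`.

Survey cells can be empty where the life table still has person-years —
the open 85+ group especially. The default borrowing rule fills an empty
cell with the nearest non-empty younger cell's proportion (the grid floor
borrows upward), flags it, and reuses the donor's denominator in the
variance so borrowed cells do not pretend to add information. Without
borrowing (`borrow = "none"`) the Sullivan sum refuses to run past a missing
cell, which is the safer behaviour for serious use with very sparse surveys.

The Sullivan estimator applies each interval's prevalence to that interval's
person-years with no within-interval age weighting. The default standard
error carries the prevalence variance only,

    Var(HLE_x) = sum_y L_y^2 pi_y (1 - pi_y) / n_y / l_x^2 ,

the usual practice when the registry (tens of thousands of person-years)
dwarfs the survey (about a thousand respondents); the Chiang-style
mortality-variance component can be added (`mortality_variance = TRUE`) and
is the analogue of Chiang's life-expectancy variance evaluated on healthy
person-years. Reported proportions (percent of remaining life in the
favourable state) are computed from unrounded expectancies and rounded to
integer percent at the end; reporting ages default to 50, 65 and 80.

## Logistic determinants

The determinants module fits maximum-likelihood logistic regressions of
each dichotomized outcome on sex, 5-year age band, SES, site, follow-up
class, stage, comorbidity and treatment, with reference levels male, the
youngest band, high SES, colon, short follow-up, stage I, no comorbidity,
surgery only. `unknown` levels stay in the model as explicit categories.
Age can alternatively enter as three broad display bands or as a continuous
centred term (used by the recovery tests). Fitting is IRLS via `stats::glm`
behind a surface that adds an explicit rank check and a separation guard:
fitted probabilities within 1e-8 of 0 or 1 together with diverging linear
predictors raise an error, because a silently divergent odds ratio is worse
than no estimate. Wald 95% intervals match the usual reporting style; no
multiplicity adjustment is applied, and significance is a display flag only.
Separation is not an abstract concern: a survey of a few hundred respondents
against ~20 dummy variables quite often has an age band with zero adverse
outcomes, and the error says so.

## The synthetic generator

The generator exists so that every pipeline stage has a ground truth. Its
mortality model is Gompertz background plus a constant stage-specific excess
from diagnosis,

    mu(a) = alpha exp(beta a) + excess(stage) ,

chosen as the simplest form with a closed-form cumulative hazard: remaining
life expectancy under it is a one-dimensional quadrature
(`analytic_life_expectancy()`), which is the oracle the life-table pipeline
is tested against. Death times are drawn by inverting the cumulative hazard
with a vectorised Newton iteration (the cumulative hazard is convex and
increasing, so the iteration is monotone after the first step).

Defaults emulate a registry survivor cohort of the kind the package targets:
14,849 persons, 53% male, stage mix roughly 26/36/25/14% (I–IV) with 4%
masked to unknown, 63% comorbid among known status, SES 32/41/27 plus small
institutionalized and unknown shares, diagnosis ages normal with mean 68
(SD 11), background `alpha = 2e-5`/yr and `beta = 0.095`/yr, and stage
excesses (0.035, 0.07, 0.14, 0.45)/yr — set so ten-year survival separates
strongly by stage and the metastatic stage lives on the order of two years.
The survey samples eligible (alive, diagnosed) persons so that about 1,300
respond; response follows a logistic model whose poor-health offset (default
−0.5 on the log-odds) encodes health-dependent nonresponse. The magnitude of
that offset is frankly arbitrary — the direction (sicker people respond
less) is well grounded, the size is not reported anywhere usable — and it is
therefore a parameter, not a claim. Item nonresponse (7% general health,
12% walking) matches the usual gap between the two items' completion rates.

Within the good mass the three favourable item levels are equiprobable, as
are the two adverse levels: only the dichotomy matters downstream, so the
split is not a modelling statement. The health-state models evaluate the
*recorded* stage (unknown behaves as reference) and the comorbidity
indicator; recovery tests therefore switch masking off.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: treatment effects on survival or health
(treatment is descriptive only), within-person health dynamics and response
shift, stoma status and symptom scales, non-proportional or time-varying
excess hazards, and any cohort trend across diagnosis years. Parameter
recovery on synthetic data shows the estimators are correct, not that the
model is true.

## Numerical and testing choices

Quadrature for the oracle integrates the survivor function to the point
where survivorship falls below 1e-12, with `rel.tol = 1e-10`. The logistic
fitter runs IRLS to `epsilon = 1e-10` within 50 iterations. One global seed
drives the generator; substreams for cohort and survey generation are
derived deterministically from it, so a run is reproducible end to end and
output bundles are identical across repeats (provenance timestamps aside).

Problem sizes in the test-suite were chosen to make Monte-Carlo bands
comfortable: 10,000-person cohorts for survivor-function checks (binomial
error under 1 percentage point), 20,000 persons for life-expectancy
recovery, 20 generator seeds for logistic coefficient recovery (requiring at
least 90% of seeds to land every coefficient within 3 Wald SE of truth). For
the life-expectancy recovery specifically, the experiment uses a 15-year
observation window and a broad age-at-diagnosis spread (normal, mean 58,
SD 16): with the cohort-emulating defaults most diagnoses arrive in the
late 60s, the youngest age bins then carry only a few hundred person-years,
and the sampling noise of `e_50` would be of the same order as the ±0.3-year
recovery band being checked. Widening the exposure design measures the same
estimand with adequate information in every bin; across repeated seeds the
design is unbiased with an `e_50` standard deviation near 0.2 years.

## Known limitations

* Sullivan stationarity, as above; no multistate extension.
* The prevalence-only default CI understates uncertainty when strata have
  few deaths; switch the Chiang term on for such strata.
* The borrowing rule is a pragmatic smoother for thin old-age survey cells;
  with a very sparse survey, prefer `borrow = "none"` and a coarser grid.
* Follow-up class is frozen at window entry; no dynamic reclassification.
* The generator's excess hazard is constant from diagnosis. Real
  registry data show declining excess with time since diagnosis; stratified
  life expectancy by follow-up time partially absorbs this, the generator
  does not reproduce it.
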