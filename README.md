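# healthexp

Sullivan-method health expectancy for cancer-registry survivor cohorts.

## What it is for

Cancer survivors live with reduced life expectancy, but years of remaining
life say nothing about how those years are spent. `healthexp` is for
epidemiologists who want to partition the remaining life of a survivor cohort
into years in good self-rated health versus poor health, and years free of
walking disability versus with disability, starting from two ordinary inputs:

1. **registry records** — one row per survivor: sex, birth and diagnosis
   dates, tumour site, pTNM stage, treatment group, comorbidity, socioeconomic
   class, vital status and exit date;
2. **a cross-sectional quality-of-life survey** — one row per respondent: the
   SF-36 general-health item (5 levels) and the SF-36 walking-limitation item
   (3 levels).

The package computes abridged period life tables from Lexis-split
person-time, age-specific prevalence of poor health and disability, and
Sullivan-method healthy life expectancy (HLE) and disability-free life
expectancy (DFLE), stratified by sex, socioeconomic status, time since
diagnosis, stage and comorbidity, plus a multivariate logistic determinants
analysis of the two outcomes. A synthetic registry/survey generator with
closed-form mortality provides ground truth for every stage.

## The method

For an observation window (say, five calendar years), each selected
survivor's follow-up is split at exact birthday instants into 5-year age
groups, giving deaths `D_x` and person-years `P_x`. The abridged life table
follows from the central death rates `m_x = D_x / P_x`:

    q_x = n_x m_x / (1 + (n_x - a_x) m_x)        (a_x = n_x/2, open group q = 1)
    l_{x+n} = l_x (1 - q_x),  d_x = l_x q_x
    L_x = n_x l_{x+n} + a_x d_x,                  L_last = l_last / m_last
    T_x = sum_{y >= x} L_y,   e_x = T_x / l_x

The survey supplies the age-specific prevalence `pi_x` of being in the
adverse state (fair/poor general health, or any walking limitation). The
Sullivan combination weights person-years by the probability of being in the
favourable state:

    HLE_x = ( sum_{y >= x} (1 - pi_y) L_y ) / l_x

with standard error carrying the binomial prevalence variance
`sum L_y^2 pi_y (1 - pi_y) / n_y / l_x^2` (a Chiang-style mortality term is
available as an option). DFLE is the same construction with the disability
prevalence. The determinants module fits maximum-likelihood logistic
regressions (adjusted odds ratios with Wald 95% CIs) of each outcome on sex,
age group, SES, site, follow-up time, stage, comorbidity and treatment.

## Worked example

Everything runs from one config; with a `simulate:` block the pipeline
generates its own registry in place of real microdata:

```r
library(healthexp)
cfg <- run_config(simulate = sim_params(seed = 1),
                  strata = c("sex", "stage"), seed = 1)
bundle <- run_pipeline(cfg)
print(bundle)
#> Health-expectancy pipeline bundle
#>    simulated 14849 persons, 1313 survey respondents
#>    selected 10377 of 14849 persons
#>    3696 deaths over 31047 person-years
#>   Overall Sullivan results:
#>  age   LE  HLE DFLE prop_HLE prop_DFLE
#>   50 9.26 7.55 7.64       82        83
#>   65 8.88 6.95 6.03       78        68
#>   80 6.40 4.77 3.26       75        51
```

A 50-year-old in this synthetic cohort can expect 9.3 further years, of
which 7.5 (82%) in good self-rated health and 7.6 (83%) without walking
limitation. Stage stratification shows the expected gradient — the
stage-specific excess hazards of the generator translate into life
expectancies from ~19 years (stage I) down to ~2.5 years (stage IV):

```r
subset(bundle$sullivan, stratum == "stage" & age == 50,
       select = c(level, LE, HLE, prop_HLE, sparse))
#>  level    LE   HLE prop_HLE sparse
#>      I 18.91 14.62       77  FALSE
#>     II 12.64 10.25       81  FALSE
#>    III  6.11  5.65       92  FALSE
#>     IV  2.50  2.50      100   TRUE
```

The stage-IV row is flagged `sparse`: almost no stage-IV survivor is alive
at the survey date, so its prevalence (and hence HLE) rests on a handful of
respondents — exactly the situation the flag exists for. Aggregate
characteristics tables can be re-analysed without microdata:

```r
summarize_counts(read_count_fixture())
#> Cohort: n = 14849; 53% male; 62% aged 65+ at diagnosis; 63% comorbid (known)
```

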