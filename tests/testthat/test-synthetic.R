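test_that("parameter validation names the offending field", {
  expect_error(sim_params(stage_probs = c(0.5, 0.5, 0.1, 0.1)), "stage_probs")
  expect_error(sim_params(sex_ratio = 1.2), "sex_ratio")
  expect_error(sim_params(stage_excess_hazard = c(-0.1, 0, 0, 0)),
               "stage_excess_hazard")
  expect_error(sim_params(window_start = "2010-01-01", window_end = "2005-01-01"),
               "window_start")
})

test_that("n_persons = 0 yields an empty cohort with the full schema", {
  co <- generate_cohort(sim_params(n_persons = 0))
  expect_equal(nrow(co), 0L)
  expect_setequal(names(co), c("person_id", "sex", "birth_date", "diagnosis_date",
                               "site", "stage", "treatment", "comorbidity",
                               "ses", "vital_status", "exit_date"))
})

test_that("generation is deterministic under a fixed seed", {
  p <- quick_params(n = 500L, seed = 42L)
  co1 <- generate_cohort(p)
  co2 <- generate_cohort(p)
  expect_identical(co1, co2)
  expect_identical(generate_survey(co1, p), generate_survey(co2, p))
  co3 <- generate_cohort(quick_params(n = 500L, seed = 43L))
  expect_false(identical(co1, co3))
})

test_that("generated dates respect the record invariants", {
  co <- generate_cohort(quick_params(n = 3000L, seed = 5L))
  expect_true(all(co$exit_date >= co$diagnosis_date))
  expect_true(all(co$diagnosis_date >= co$birth_date))
  expect_true(all(co$stage %in% c("I", "II", "III", "IV", "unknown")))
  expect_true(all(co$ses %in% c("high", "middle", "low", "institutionalized",
                                "unknown")))
})

test_that("10-year survival from age 60 matches the closed-form Gompertz survivor", {
  # pure background: alpha = 1e-5/yr, beta = 0.1/yr, diagnosis at 60, no excess
  p <- sim_params(n_persons = 10000L, seed = 3L,
                  background_alpha = 1e-5, background_beta = 0.1,
                  stage_excess_hazard = c(0, 0, 0, 0), stage_unknown_prob = 0,
                  diagnosis_age_mean = 60, diagnosis_age_sd = 1e-9,
                  diagnosis_start = "1990-01-01", diagnosis_end = "1990-01-01",
                  followup_end = "2080-01-01", window_end = "2080-01-01")
  co <- generate_cohort(p)
  t_death <- as.numeric(co$exit_date - co$diagnosis_date) / YD
  expect_true(all(co$vital_status == "dead"))      # horizon far beyond everyone
  s10_hat <- mean(t_death > 10)                    # no censoring: KM = empirical
  s10_true <- exp(-(1e-5 / 0.1) * (exp(0.1 * 70) - exp(0.1 * 60)))
  expect_lt(abs(s10_hat - s10_true), 0.02)
})

test_that("with zero excess hazard, survival time does not depend on stage", {
  p <- sim_params(n_persons = 4000L, seed = 9L,
                  stage_excess_hazard = c(0, 0, 0, 0), stage_unknown_prob = 0,
                  followup_end = "2080-01-01", window_end = "2080-01-01")
  co <- generate_cohort(p)
  t_death <- as.numeric(co$exit_date - co$diagnosis_date) / YD
  kw <- stats::kruskal.test(t_death, factor(co$stage))
  expect_gt(kw$p.value, 0.005)
})

test_that("survey honours eligibility, the response model, and degenerate logits", {
  p <- quick_params(n = 1000L, seed = 21L)
  co <- generate_cohort(p)
  sv <- generate_survey(co, p)
  joined <- co[match(sv$person_id, co$person_id), ]
  alive <- (joined$vital_status == "censored" & joined$exit_date >= p$survey_date) |
    (joined$vital_status == "dead" & joined$exit_date > p$survey_date)
  expect_true(all(alive))
  expect_true(all(joined$diagnosis_date <= p$survey_date))

  # intercept -> -inf: nobody reports fair or poor
  p_good <- quick_params(n = 1000L, seed = 21L,
                         poor_health_coefs = c(-30, 0, 0, 0, 0, 0),
                         item_missing_general = 0)
  sv_good <- generate_survey(generate_cohort(p_good), p_good)
  expect_true(all(sv_good$general_health_item %in%
                    c("excellent", "very_good", "good")))

  # survey_fraction = 0: empty survey
  p0 <- quick_params(n = 200L, seed = 21L, survey_fraction = 0)
  expect_equal(nrow(generate_survey(generate_cohort(p0), p0)), 0L)
})

test_that("intercept-only prevalence model reproduces its binomial mean", {
  p <- sim_params(n_persons = 9000L, seed = 8L,
                  stage_excess_hazard = c(0.01, 0.01, 0.01, 0.01),
                  poor_health_coefs = c(0, 0, 0, 0, 0, 0),   # logit^-1(0) = 0.5
                  survey_fraction = 1, response_coefs = c(30, 0),
                  item_missing_general = 0)
  co <- generate_cohort(p)
  sv <- generate_survey(co, p)
  expect_gt(nrow(sv), 5000L)
  frac_poor <- mean(sv$general_health_item %in% c("fair", "poor"))
  expect_lt(abs(frac_poor - 0.5), 0.02)
})

test_that("analytic life expectancy matches closed forms and a Riemann oracle", {
  expect_equal(analytic_life_expectancy(0.1, 0, 0, 60), 10, tolerance = 1e-6)
  expect_equal(analytic_life_expectancy(0.05, 0, 0, 60), 20, tolerance = 1e-6)
  # brute-force 0.01-year Riemann sum, alpha = 1e-4, beta = 0.09, age 50
  alpha <- 1e-4; beta <- 0.09; age <- 50
  dt <- 0.01
  t <- seq(dt / 2, 120, by = dt)   # midpoint rule
  H <- (alpha / beta) * (exp(beta * (age + t)) - exp(beta * age))
  riemann <- sum(exp(-H) * dt)
  quad <- analytic_life_expectancy(alpha, beta, 0, age)
  expect_lt(abs(quad - riemann) / riemann, 5e-4)
  expect_error(analytic_life_expectancy(0, 0.1, 0), "zero")
})
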