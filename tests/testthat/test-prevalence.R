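grid5 <- age_grid()

# survey respondents placed at chosen ages with chosen items
make_survey_at <- function(ages, gh = "good", walk = "not_limited",
                           survey_date = as.Date("2009-07-01")) {
  n <- length(ages)
  ids <- sprintf("s%03d", seq_len(n))
  cohort <- do.call(rbind, lapply(seq_len(n), function(i)
    make_person(birthday_of(survey_date, -ages[i]), "2000-01-01", "2009-12-31",
                id = ids[i])))
  survey <- data.frame(person_id = ids, survey_date = survey_date,
                       general_health_item = rep_len(gh, n),
                       walking_item = rep_len(walk, n),
                       stringsAsFactors = FALSE)
  list(cohort = cohort, survey = survey)
}

test_that("general-health dichotomization follows the good/poor split", {
  expect_equal(dichotomize_general_health(
    c("excellent", "very_good", "good", "fair", "poor", "missing")),
    c("good", "good", "good", "poor", "poor", "missing"))
  expect_error(dichotomize_general_health("splendid"), "unknown")
})

test_that("walking dichotomization counts any limitation as limited", {
  expect_equal(dichotomize_walking(
    c("very_limited", "little_limited", "not_limited", "missing")),
    c("limited", "limited", "not_limited", "missing"))
  expect_error(dichotomize_walking("crawling"), "unknown")
})

test_that("prevalence matches the hand binomial computation", {
  fx <- make_survey_at(rep(62, 10), gh = c(rep("fair", 3), rep("good", 7)))
  pt <- suppressWarnings(
    prevalence_by_age(fx$survey, fx$cohort, grid5, "poor_health"))
  row <- pt[pt$age_group == "60-64", ]
  expect_equal(row$n, 10L)
  expect_equal(row$k, 3L)
  expect_equal(row$pi, 0.3)
  expect_equal(row$se, sqrt(0.21 / 10), tolerance = 1e-12)
})

test_that("missing outcomes and under-age respondents are excluded", {
  fx <- make_survey_at(c(62, 62, 62, 45), gh = c("fair", "good", "missing", "poor"))
  pt <- suppressWarnings(
    prevalence_by_age(fx$survey, fx$cohort, grid5, "poor_health", borrow = "none"))
  expect_equal(sum(pt$n, na.rm = TRUE), 2L)   # missing item and age<50 dropped
  expect_equal(pt$pi[pt$age_group == "60-64"], 0.5)
})

test_that("all-favourable answers give zero prevalence everywhere observed", {
  ages <- rep(c(52, 57, 62, 67, 72, 77, 82, 87), each = 3)
  fx <- make_survey_at(ages, gh = "excellent")
  pt <- prevalence_by_age(fx$survey, fx$cohort, grid5, "poor_health")
  expect_true(all(pt$pi == 0))
  expect_false(any(pt$borrowed))
})

test_that("empty cells borrow the nearest younger non-empty cell and are flagged", {
  fx <- make_survey_at(c(62, 62, 77), gh = c("fair", "good", "good"))
  expect_warning(
    pt <- prevalence_by_age(fx$survey, fx$cohort, grid5, "poor_health"),
    "filled")
  expect_equal(pt$pi[pt$age_group == "60-64"], 0.5)
  expect_true(pt$borrowed[pt$age_group == "85+"])
  expect_equal(pt$pi[pt$age_group == "85+"], 0)     # donor: 75-79
  expect_equal(pt$pi[pt$age_group == "70-74"], 0.5) # donor below: 60-64
  # the grid floor borrows upward when no younger cell exists
  expect_true(pt$borrowed[pt$age_group == "50-54"])
  expect_equal(pt$pi[pt$age_group == "50-54"], 0.5)

  pt2 <- prevalence_by_age(fx$survey, fx$cohort, grid5, "poor_health",
                           borrow = "none")
  expect_true(is.na(pt2$pi[pt2$age_group == "85+"]))
})

test_that("prevalence is invariant to respondent order and join errors are loud", {
  fx <- make_survey_at(c(62, 71, 62, 83), gh = c("fair", "good", "good", "poor"))
  pt1 <- suppressWarnings(prevalence_by_age(fx$survey, fx$cohort, grid5, "poor_health"))
  shuffled <- fx$survey[c(3, 1, 4, 2), ]
  pt2 <- suppressWarnings(prevalence_by_age(shuffled, fx$cohort, grid5, "poor_health"))
  expect_equal(pt1, pt2)

  orphan <- fx$survey
  orphan$person_id[1] <- "ghost"
  expect_error(suppressWarnings(
    prevalence_by_age(orphan, fx$cohort, grid5, "poor_health")), "ghost")
})

test_that("an intercept-only generator yields a flat prevalence profile", {
  p <- sim_params(n_persons = 8000L, seed = 29L,
                  poor_health_coefs = c(stats::qlogis(0.3), 0, 0, 0, 0, 0),
                  survey_fraction = 1, response_coefs = c(30, 0),
                  item_missing_general = 0)
  co <- generate_cohort(p)
  sv <- generate_survey(co, p)
  f <- cohort_filter()
  sel <- suppressMessages(select_alive_in_window(co, f))
  svs <- sv[sv$person_id %in% sel$person_id, ]
  pt <- suppressWarnings(prevalence_by_age(svs, sel, grid5, "poor_health"))
  obs <- pt[!pt$borrowed & pt$n >= 50, ]
  expect_true(all(abs(obs$pi - 0.3) < 4 * obs$se + 0.02))
})
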