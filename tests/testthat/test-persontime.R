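grid5 <- age_grid()
day <- 1 / YD

test_that("a person observed through a 5-year window contributes 5 person-years", {
  ws <- as.Date("2005-01-01")
  we <- as.Date(round(as.numeric(ws) + 5 * YD), origin = "1970-01-01")
  f <- cohort_filter(ws, we)
  p <- make_person(birthday_of(ws, -60), "2000-01-01", we, "censored")
  sp <- split_person_time(p, f, grid5)
  # date rounding can leave a sliver of a day in a neighbouring group
  main <- sp[sp$person_years > 2 * day, ]
  expect_equal(main$age_group, "60-64")
  expect_equal(main$person_years, 5, tolerance = 2 * day)
  expect_equal(sum(sp$person_years), 5, tolerance = 2 * day)
  expect_false(any(sp$death))
})

test_that("exposure splits at the age-group boundary crossed mid-window", {
  ws <- as.Date("2005-01-01")
  we <- as.Date(round(as.numeric(ws) + 5 * YD), origin = "1970-01-01")
  f <- cohort_filter(ws, we)
  p <- make_person(birthday_of(ws, -63), "2000-01-01", we, "censored")
  sp <- split_person_time(p, f, grid5)
  expect_equal(sp$age_group, c("60-64", "65-69"))
  expect_equal(sp$person_years, c(2, 3), tolerance = 2 * day)
})

test_that("a death is attributed to the segment containing the exit", {
  ws <- as.Date("2005-01-01")
  f <- cohort_filter(ws, "2009-12-31")
  exit <- as.Date(round(as.numeric(ws) + 2.5 * YD), origin = "1970-01-01")
  p <- make_person(birthday_of(ws, -57.5), "2000-01-01", exit, "dead")
  sp <- split_person_time(p, f, grid5)
  expect_equal(sp$age_group, "55-59")
  expect_equal(sp$person_years, 2.5, tolerance = 2 * day)
  expect_true(sp$death)
})

test_that("aggregation reproduces hand-computed toy exposures", {
  ws <- as.Date("2005-01-01")
  we <- as.Date(round(as.numeric(ws) + 5 * YD), origin = "1970-01-01")
  f <- cohort_filter(ws, we)
  exit_d <- as.Date(round(as.numeric(ws) + 2.5 * YD), origin = "1970-01-01")
  co <- rbind(
    make_person(birthday_of(ws, -63), "2000-01-01", we, "censored", id = "a"),
    make_person(birthday_of(ws, -57.5), "2000-01-01", exit_d, "dead", id = "b"))
  ex <- aggregate_exposure(co, f, grid5)
  expect_equal(ex$age_group, grid5$labels)
  expect_equal(ex$deaths, c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(ex$person_years, c(0, 2.5, 2, 3, 0, 0, 0, 0), tolerance = 1e-2)

  single <- aggregate_exposure(co[1, ], f, grid5)
  expect_equal(sum(single$deaths), 0L)
  expect_equal(sum(single$person_years), 5, tolerance = 2 * day)
})

test_that("an empty cohort and a zero-eligible person yield zero exposure", {
  f <- cohort_filter()
  ex <- aggregate_exposure(generate_cohort(sim_params(n_persons = 0)), f, grid5)
  expect_true(all(ex$deaths == 0) && all(ex$person_years == 0))
  # exits before the window: zero eligible time, empty split
  p <- make_person("1930-01-01", "1999-01-01", "2003-01-01", "dead")
  expect_equal(nrow(split_person_time(p, f, grid5)), 0L)
})

test_that("person-years and deaths are conserved on 1,000 synthetic persons", {
  f <- cohort_filter()
  co <- suppressMessages(select_alive_in_window(
    generate_cohort(quick_params(n = 2500L, seed = 13L)), f))
  co <- co[seq_len(1000L), ]
  ex <- aggregate_exposure(co, f, grid5)

  # conservation against durations recomputed straight from the dates
  start <- pmax(as.numeric(f$window_start), as.numeric(co$diagnosis_date),
                as.numeric(co$birth_date) + 50 * YD)
  end <- pmin(as.numeric(co$exit_date), as.numeric(f$window_end))
  expect_equal(sum(ex$person_years), sum(pmax(0, end - start)) / YD,
               tolerance = 1e-9)
  in_window_deaths <- sum(co$vital_status == "dead" &
                            as.numeric(co$exit_date) <= as.numeric(f$window_end) &
                            end > start)
  expect_equal(sum(ex$deaths), in_window_deaths)
})

test_that("exposure agrees with the day-by-day oracle person by person", {
  f <- cohort_filter()
  co <- suppressMessages(select_alive_in_window(
    generate_cohort(quick_params(n = 1500L, seed = 17L)), f))
  co <- co[seq_len(min(1000L, nrow(co))), ]
  worst <- 0
  for (i in seq_len(nrow(co))) {
    got <- exposure_core_for_test(co[i, ], f, grid5)
    want <- oracle_person_exposure(co[i, ], f, grid5)
    worst <- max(worst, max(abs(got$person_years - want$person_years)))
    expect_identical(got$deaths, want$deaths)
  }
  expect_lt(worst, 1.5 * day)   # at most one boundary day of slack per interval
})

test_that("refining to a 1-year grid and re-coarsening reproduces 5-year exposures", {
  f <- cohort_filter()
  co <- suppressMessages(select_alive_in_window(
    generate_cohort(quick_params(n = 800L, seed = 19L)), f))
  grid1 <- age_grid(50:85)
  ex5 <- aggregate_exposure(co, f, grid5)
  ex1 <- aggregate_exposure(co, f, grid1)
  groups <- findInterval(grid1$lower, grid5$lower)
  expect_equal(as.numeric(tapply(ex1$person_years, groups, sum)),
               ex5$person_years, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(as.numeric(tapply(ex1$deaths, groups, sum)), ex5$deaths,
               ignore_attr = TRUE)
})
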