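test_that("the shipped characteristics fixture reproduces its summary shares", {
  counts <- read_count_fixture()
  s <- summarize_counts(counts)
  expect_equal(s$derived$n_total, 14849L)
  expect_equal(round(s$derived$percent_male), 53)
  expect_equal(round(s$derived$percent_age65plus_dx), 62)
  expect_equal(round(s$derived$percent_comorbid_known), 63)
})

test_that("column percentages sum to 100 within rounding for each variable", {
  s <- summarize_counts(read_count_fixture())
  for (v in unique(s$counts$variable)) {
    sub <- s$counts[s$counts$variable == v, ]
    expect_equal(sum(sub$pct_male), 100, tolerance = 0.5)
    expect_equal(sum(sub$pct_female), 100, tolerance = 0.5)
  }
})

test_that("cohort_summary on microdata matches direct tabulation", {
  p <- quick_params(n = 3000L, seed = 53L)
  co <- generate_cohort(p)
  f <- cohort_filter()
  sel <- suppressMessages(select_alive_in_window(co, f))
  s <- cohort_summary(sel, f)
  expect_equal(s$derived$n_total, nrow(sel))
  expect_equal(s$derived$percent_male, 100 * mean(sel$sex == "male"))
  known <- sel$comorbidity != "unknown"
  expect_equal(s$derived$percent_comorbid_known,
               100 * sum(sel$comorbidity == "1plus") / sum(known))
  empty <- cohort_summary(generate_cohort(sim_params(n_persons = 0)), f)
  expect_equal(empty$derived$n_total, 0L)
})

test_that("Kaplan-Meier reproduces the hand product-limit computation", {
  base <- as.Date("2000-01-01")
  co <- do.call(rbind, lapply(1:4, function(i)
    make_person("1940-01-01", base,
                as.Date(round(as.numeric(base) + i * YD), origin = "1970-01-01"),
                "dead", id = paste0("k", i))))
  km <- km_survival(co, horizons = c(0, 1, 2.5, 5))
  expect_equal(km$surv[km$time == 2.5], 0.5, tolerance = 1e-6)
  expect_equal(km$surv[km$time == 5], 0, tolerance = 1e-6)

  cens <- do.call(rbind, lapply(1:10, function(i)
    make_person("1940-01-01", base,
                as.Date(round(as.numeric(base) + 6 * YD), origin = "1970-01-01"),
                "censored", id = paste0("c", i))))
  km2 <- km_survival(cens, horizons = 5)
  expect_equal(km2$surv, 1)
  expect_equal(attr(km2, "degenerate"), "II")
})

test_that("a heavy stage-IV excess hazard orders the survival curves", {
  p <- sim_params(n_persons = 6000L, seed = 59L,
                  stage_excess_hazard = c(0.02, 0.04, 0.08, 0.8),
                  stage_unknown_prob = 0)
  co <- generate_cohort(p)
  km <- km_survival(co, horizons = 1:10, window = c("2000-01-01", "2009-12-31"))
  s1 <- km$surv[km$group == "I"]
  s4 <- km$surv[km$group == "IV"]
  expect_true(all(s4 < s1))
})

test_that("the pipeline is deterministic, validates its config, and keeps HLE <= LE", {
  cfg <- run_config(simulate = quick_params(n = 3000L, seed = 61L),
                    strata = c("sex", "stage"), seed = 61L)
  b1 <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  b2 <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  drop_ts <- function(b) { b$provenance$timestamp <- NULL; b }
  expect_identical(drop_ts(unclass(b1)), drop_ts(unclass(b2)))
  expect_true(all(b1$sullivan$HLE <= b1$sullivan$LE + 1e-9, na.rm = TRUE))
  expect_true(all(b1$sullivan$DFLE <= b1$sullivan$LE + 1e-9, na.rm = TRUE))

  expect_error(run_config(cohort_path = tempfile()), "must exist")
  expect_error(run_config(simulate = quick_params(), ages = c(50, 52)),
               "grid boundaries")
})

test_that("pipeline outputs land on disk with a provenance header", {
  dir <- withr::local_tempdir()
  cfg <- run_config(simulate = quick_params(n = 6000L, seed = 67L,
                                            survey_fraction = 0.6),
                    strata = "sex", output_dir = dir, seed = 67L)
  b <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  files <- list.files(dir)
  expect_true(all(c("life_table.csv", "sullivan.csv", "results.json") %in% files))
  first <- readLines(file.path(dir, "life_table.csv"), n = 1)
  expect_match(first, "^# healthexp .*config [0-9a-f]+")
  lt <- utils::read.csv(file.path(dir, "life_table.csv"), comment.char = "#")
  expect_equal(nrow(lt), 8L)
})

test_that("a YAML config drives the same pipeline", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 71",
    "ages: [50, 65]",
    "strata: [sex]",
    "simulate:",
    "  n_persons: 5000",
    "  survey_fraction: 0.7",
    "  seed: 71"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$ages, c(50, 65))
  b <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  expect_s3_class(b, "hle_bundle")
  expect_true(nrow(b$sullivan) >= 2)
})
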