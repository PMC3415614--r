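## Orchestration: cohort characteristics tables, Kaplan-Meier survival by
## stage, and the end-to-end pipeline driven by one config object.

# Polynomial rolling fingerprint of a serialised R object (mod 2^31 - 1);
# a provenance stamp, not a cryptographic hash.
config_fingerprint <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2L))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 257 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}

AGE_DX_BANDS <- c("<50", "50-64", "65-79", "80+")

band_age <- function(age, include_under50 = TRUE) {
  breaks <- if (include_under50) c(-Inf, 50, 65, 80, Inf) else c(50, 65, 80, Inf)
  labels <- if (include_under50) AGE_DX_BANDS else AGE_DX_BANDS[-1L]
  as.character(cut(age, breaks, labels = labels, right = FALSE))
}

#' Cohort characteristics table
#'
#' Frequency table by sex over age at diagnosis, attained age in the window,
#' SES, site, stage, treatment and comorbidity, with column percentages, plus
#' the derived summary shares: percent male, percent aged 65+ at diagnosis,
#' and percent with comorbidity among those of known comorbidity status.
#'
#' @param cohort Selected cohort data.frame.
#' @param filter A [cohort_filter()] (for the attained-age-in-window bands,
#'   taken at each person's last instant inside the window).
#' @return List of class `cohort_summary`: `counts` (long data.frame:
#'   `variable, level, male, female, pct_male, pct_female`) and `derived`
#'   (named list of unrounded percentages).
#' @export
cohort_summary <- function(cohort, filter) {
  stopifnot(inherits(filter, "cohort_filter"))
  age_dx <- years_between(cohort$birth_date, cohort$diagnosis_date)
  last_in_window <- pmin(as.numeric(cohort$exit_date),
                         as.numeric(filter$window_end))
  age_win <- (last_in_window - as.numeric(cohort$birth_date)) / YEAR_DAYS
  vars <- list(
    age_at_diagnosis = factor(band_age(age_dx), levels = AGE_DX_BANDS),
    age_in_window = factor(band_age(age_win, FALSE), levels = AGE_DX_BANDS[-1L]),
    ses = factor(cohort$ses, levels = SES_LEVELS),
    site = factor(cohort$site, levels = SITE_LEVELS),
    stage = factor(cohort$stage, levels = STAGE_LEVELS),
    treatment = factor(cohort$treatment, levels = TREATMENT_LEVELS),
    comorbidity = factor(cohort$comorbidity, levels = COMORB_LEVELS))
  male <- cohort$sex == "male"
  counts <- do.call(rbind, lapply(names(vars), function(v) {
    tab_m <- table(vars[[v]][male])
    tab_f <- table(vars[[v]][!male])
    data.frame(variable = v, level = names(tab_m),
               male = as.integer(tab_m), female = as.integer(tab_f),
               stringsAsFactors = FALSE)
  }))
  summarize_counts(counts)
}

#' Derived summary shares from a characteristics count table
#'
#' Works from aggregate counts alone (no microdata needed), so printed
#' characteristics tables can be re-analysed as fixtures. The count table has
#' columns `variable, level, male, female`; `age_at_diagnosis` must be a
#' complete partition of the cohort, and a `comorbidity` variable with levels
#' `0`, `1plus`, `unknown` supplies the comorbidity share among known.
#'
#' @param counts Data.frame as described above.
#' @return List of class `cohort_summary` with `counts` (percentage columns
#'   added) and `derived`: `n_total`, `percent_male`, `percent_age65plus_dx`,
#'   `percent_comorbid_known` (unrounded).
#' @export
summarize_counts <- function(counts) {
  stopifnot(all(c("variable", "level", "male", "female") %in% names(counts)))
  age <- counts[counts$variable == "age_at_diagnosis", ]
  if (!nrow(age)) stop("counts must include an 'age_at_diagnosis' partition",
                       call. = FALSE)
  n_male <- sum(age$male)
  n_female <- sum(age$female)
  n_total <- n_male + n_female
  older <- age$level %in% c("65-79", "80+")
  pct_65plus <- 100 * sum(age$male[older] + age$female[older]) / n_total
  com <- counts[counts$variable == "comorbidity", ]
  pct_comorb <- if (nrow(com)) {
    known <- com$level %in% c("0", "1plus")
    100 * sum(com$male[com$level == "1plus"] + com$female[com$level == "1plus"]) /
      sum(com$male[known] + com$female[known])
  } else NA_real_
  counts$pct_male <- if (n_male > 0) 100 * counts$male / n_male else 0
  counts$pct_female <- if (n_female > 0) 100 * counts$female / n_female else 0
  structure(list(counts = counts,
                 derived = list(n_total = n_total,
                                percent_male = 100 * n_male / n_total,
                                percent_age65plus_dx = pct_65plus,
                                percent_comorbid_known = pct_comorb)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  d <- x$derived
  cat(sprintf("Cohort: n = %d; %d%% male; %d%% aged 65+ at diagnosis; %d%% comorbid (known)\n",
              d$n_total, round(d$percent_male), round(d$percent_age65plus_dx),
              round(d$percent_comorbid_known)))
  invisible(x)
}

#' Read a characteristics count fixture
#'
#' Loads an aggregate count table (columns `variable, level, male, female`)
#' such as a printed cohort-characteristics table, for use with
#' [summarize_counts()].
#'
#' @param path CSV path; defaults to the registry characteristics table
#'   shipped with the package.
#' @return Data.frame of counts.
#' @export
read_count_fixture <- function(path = system.file("extdata", "table1_counts.csv",
                                                  package = "healthexp")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival by stage
#'
#' Product-limit estimate of survival from diagnosis, right-censored at the
#' end of follow-up, optionally restricted to persons alive inside an
#' observation window (entering the risk set late, at the window start).
#'
#' @param cohort Cohort data.frame.
#' @param group Column name to stratify the curves on (default `"stage"`).
#' @param horizons Yearly horizons (years from diagnosis) at which to report.
#' @param window Optional `c(start, end)` dates restricting follow-up.
#' @return Data.frame: `group, time, surv, n_risk, n_event`, plus a
#'   `degenerate` attribute naming groups with no observed events.
#' @export
km_survival <- function(cohort, group = "stage", horizons = 0:10,
                        window = NULL) {
  dx <- as.numeric(cohort$diagnosis_date)
  exit <- as.numeric(cohort$exit_date)
  if (is.null(window)) {
    entry <- rep(0, nrow(cohort))
    stop_t <- (exit - dx) / YEAR_DAYS
    event <- as.integer(cohort$vital_status == "dead")
  } else {
    ws <- as.numeric(as_date_strict(window[1], "window start"))
    we <- as.numeric(as_date_strict(window[2], "window end"))
    entry <- pmax(0, ws - dx) / YEAR_DAYS
    stop_t <- (pmin(exit, we) - dx) / YEAR_DAYS
    event <- as.integer(cohort$vital_status == "dead" & exit <= we)
  }
  keep <- stop_t > entry
  g <- factor(cohort[[group]][keep])
  # zero-length intervals and ties at 0 are handled by survfit itself
  fit <- survival::survfit(
    survival::Surv(entry[keep], stop_t[keep], event[keep]) ~ g)
  s <- summary(fit, times = horizons, extend = TRUE)
  strata_lab <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time)) else
    sub("^g=", "", as.character(s$strata))
  out <- data.frame(group = strata_lab, time = s$time, surv = s$surv,
                    n_risk = s$n.risk, n_event = s$n.event,
                    stringsAsFactors = FALSE)
  ev <- tapply(event[keep], g, sum)
  attr(out, "degenerate") <- names(ev)[!is.na(ev) & ev == 0]
  out
}

#' Pipeline run configuration
#'
#' @param cohort_path,survey_path CSV inputs; not needed when `simulate` is
#'   given.
#' @param output_dir Directory for CSV/JSON outputs (`NULL`: in-memory only).
#' @param filter A [cohort_filter()].
#' @param grid An [age_grid()].
#' @param ages Reporting ages; must be grid boundaries.
#' @param strata Stratum variables for the Sullivan tables.
#' @param simulate Optional [sim_params()] block: generate inputs instead of
#'   reading them.
#' @param seed Integer seed recorded in provenance (the simulation block
#'   carries its own).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, survey_path = NULL,
                       output_dir = NULL,
                       filter = cohort_filter(),
                       grid = age_grid(),
                       ages = c(50, 65, 80),
                       strata = c("sex", "ses", "followup", "stage", "comorbidity"),
                       simulate = NULL, seed = 1L) {
  if (is.null(simulate)) {
    for (p in c(cohort_path, survey_path))
      if (is.null(p) || !file.exists(p))
        stop("cohort_path and survey_path must exist when no simulation block is given",
             call. = FALSE)
  } else stopifnot(inherits(simulate, "sim_params"))
  if (!all(ages %in% grid$lower))
    stop("reporting ages must be grid boundaries", call. = FALSE)
  structure(list(cohort_path = cohort_path, survey_path = survey_path,
                 output_dir = output_dir, filter = filter, grid = grid,
                 ages = ages, strata = strata, simulate = simulate,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; `filter:`, `grid:` and
#' `simulate:` are nested blocks passed to [cohort_filter()], [age_grid()]
#' and [sim_params()].
#'
#' @param path YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(cohort_path = y$cohort_path, survey_path = y$survey_path,
             output_dir = y$output_dir,
             filter = do.call(cohort_filter, y$filter %||% list()),
             grid = do.call(age_grid, y$grid %||% list()),
             ages = y$ages %||% c(50, 65, 80),
             strata = y$strata %||% c("sex", "ses", "followup", "stage", "comorbidity"),
             simulate = if (!is.null(y$simulate)) do.call(sim_params, y$simulate),
             seed = y$seed %||% 1L)
}

write_with_provenance <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# healthexp %s | config %s | %s",
                     provenance$version, provenance$config_hash,
                     provenance$timestamp), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full health-expectancy pipeline
#'
#' Simulate (or read) the registry cohort and survey, apply the inclusion
#' rules, split person-time, build the life table, estimate age-specific
#' prevalence, compute Sullivan HLE/DFLE overall and per stratum, fit the
#' logistic determinants models for both outcomes, and assemble the cohort
#' characteristics and Kaplan-Meier summaries. Deterministic given the seed;
#' every output file carries a provenance header with the config hash.
#'
#' @param config A [run_config()].
#' @return List of class `hle_bundle`: `cohort_summary`, `exposure`,
#'   `life_table`, `prevalence` (both outcomes), `sullivan` (stratified
#'   table), `determinants` (both outcomes), `km`, `log`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message("pipeline: ", line)
  }
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(config$simulate)) {
    cohort <- stage_wrap("simulate", generate_cohort(config$simulate))
    survey <- stage_wrap("simulate", generate_survey(cohort, config$simulate))
    note("simulated %d persons, %d survey respondents", nrow(cohort), nrow(survey))
  } else {
    cohort <- stage_wrap("read", read_cohort(config$cohort_path))
    survey <- stage_wrap("read", read_survey(config$survey_path))
    note("read %d persons, %d survey rows", nrow(cohort), nrow(survey))
  }
  selected <- stage_wrap("select", suppressMessages(
    select_alive_in_window(cohort, config$filter)))
  note("selected %d of %d persons", nrow(selected), nrow(cohort))
  survey_sel <- survey[survey$person_id %in% selected$person_id, , drop = FALSE]

  expo <- stage_wrap("persontime",
                     aggregate_exposure(selected, config$filter, config$grid))
  note("%d deaths over %.0f person-years", sum(expo$deaths), sum(expo$person_years))
  lt <- stage_wrap("lifetable", build_life_table(
    suppressMessages(death_rates(expo)), config$grid))
  prev_h <- stage_wrap("prevalence", suppressWarnings(
    prevalence_by_age(survey_sel, selected, config$grid, "poor_health")))
  prev_d <- stage_wrap("prevalence", suppressWarnings(
    prevalence_by_age(survey_sel, selected, config$grid, "disability")))
  sull <- stage_wrap("sullivan", rbind(
    stratified_sullivan(selected, survey_sel, config$filter, config$grid,
                        character(), config$ages),
    if (length(config$strata))
      stratified_sullivan(selected, survey_sel, config$filter, config$grid,
                          config$strata, config$ages)))
  det <- stage_wrap("determinants", list(
    poor_health = suppressWarnings(
      determinants_table(survey_sel, selected, config$filter, "poor_health")),
    disability = suppressWarnings(
      determinants_table(survey_sel, selected, config$filter, "disability"))))
  summ <- stage_wrap("summary", cohort_summary(selected, config$filter))
  km <- stage_wrap("km", km_survival(selected))

  provenance <- list(version = as.character(utils::packageVersion("healthexp")),
                     config_hash = config_fingerprint(
                       config[setdiff(names(config), "output_dir")]),
                     seed = config$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  bundle <- structure(list(cohort_summary = summ, exposure = expo,
                           life_table = lt,
                           prevalence = list(poor_health = prev_h, disability = prev_d),
                           sullivan = sull, determinants = det, km = km,
                           log = log, provenance = provenance),
                      class = "hle_bundle")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(df, name)
      write_with_provenance(as.data.frame(df),
                            file.path(config$output_dir, name), provenance)
    out(expo, "exposure.csv")
    out(lt, "life_table.csv")
    out(prev_h, "prevalence_poor_health.csv")
    out(prev_d, "prevalence_disability.csv")
    out(sull, "sullivan.csv")
    out(det$poor_health, "or_poor_health.csv")
    out(det$disability, "or_disability.csv")
    out(summ$counts, "cohort_characteristics.csv")
    out(km, "km_survival.csv")
    jsonlite::write_json(list(provenance = provenance, sullivan = sull),
                         file.path(config$output_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    note("wrote outputs to %s", config$output_dir)
  }
  bundle
}

#' @export
print.hle_bundle <- function(x, ...) {
  cat("Health-expectancy pipeline bundle\n")
  cat("  ", paste(x$log, collapse = "\n   "), "\n")
  overall <- x$sullivan[x$sullivan$stratum == "all", ]
  if (nrow(overall)) {
    cat("  Overall Sullivan results:\n")
    print.data.frame(format(overall[c("age", "LE", "HLE", "DFLE",
                                      "prop_HLE", "prop_DFLE")], digits = 3),
                     row.names = FALSE)
  }
  invisible(x)
}
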