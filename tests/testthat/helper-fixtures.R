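# Shared fixtures: toy persons, a white-box prevalence table, and the
# day-by-day person-time oracle used by the conservation properties.

YD <- 365.2425

make_person <- function(birth, diagnosis, exit, vital = "censored",
                        sex = "male", site = "colon", stage = "II",
                        treatment = "surgery_only", comorbidity = "0",
                        ses = "middle", id = "p1") {
  data.frame(person_id = id, sex = sex,
             birth_date = as.Date(birth), diagnosis_date = as.Date(diagnosis),
             site = site, stage = stage, treatment = treatment,
             comorbidity = comorbidity, ses = ses, vital_status = vital,
             exit_date = as.Date(exit), stringsAsFactors = FALSE)
}

# Date at which a person born on `birth` attains `age` years (nearest day).
birthday_of <- function(birth, age) {
  as.Date(round(as.numeric(as.Date(birth)) + age * YD), origin = "1970-01-01")
}

# A prevalence table with prescribed proportions, for exercising the Sullivan
# combination at exact prevalences the survey path cannot always produce.
make_prev <- function(grid, pi, n = 100L, outcome = "poor_health") {
  k <- length(grid$lower)
  pi <- rep_len(pi, k)
  n <- rep_len(n, k)
  out <- data.frame(age_group = grid$labels, n = n, k = round(pi * n),
                    pi = pi, se = sqrt(pi * (1 - pi) / n), borrowed = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("prevalence_table", "data.frame")
  attr(out, "grid") <- grid
  attr(out, "outcome") <- outcome
  out
}

# Brute-force oracle: walk through follow-up one day at a time, assigning each
# day-sized chunk to the age group containing the age at the chunk's start.
oracle_person_exposure <- function(person, filter, grid) {
  ws <- as.numeric(filter$window_start)
  we <- as.numeric(filter$window_end)
  birth <- as.numeric(person$birth_date)
  start <- max(ws, as.numeric(person$diagnosis_date),
               birth + filter$min_age_in_window * YD)
  end <- min(as.numeric(person$exit_date), we)
  k <- length(grid$lower)
  py <- numeric(k)
  death <- integer(k)
  if (end > start) {
    ts <- seq(start, end, by = 1)
    if (ts[length(ts)] < end) ts <- c(ts, end)
    seg_start <- ts[-length(ts)]
    seg_len <- diff(ts)
    idx <- findInterval((seg_start - birth) / YD, grid$lower)
    ok <- idx >= 1 & idx <= k
    py <- as.numeric(tapply(seg_len[ok] / YD, factor(idx[ok], levels = 1:k), sum))
    py[is.na(py)] <- 0
    if (person$vital_status == "dead" && as.numeric(person$exit_date) <= we) {
      di <- findInterval((end - birth) / YD, grid$lower)
      if (di >= 1 && di <= k) death[di] <- 1L
    }
  }
  list(person_years = py, deaths = death)
}

# Dense (all-intervals) view of split_person_time for oracle comparison.
exposure_core_for_test <- function(person, filter, grid) {
  sp <- split_person_time(person, filter, grid)
  py <- numeric(length(grid$lower))
  deaths <- integer(length(grid$lower))
  idx <- match(sp$age_group, grid$labels)
  py[idx] <- sp$person_years
  deaths[idx] <- as.integer(sp$death)
  list(person_years = py, deaths = deaths)
}

# Small, fast synthetic scenario shared by several tests. The survey fraction
# is raised so that cohorts small enough to be fast still yield enough
# respondents per covariate level for the regression stages.
quick_params <- function(n = 2000L, seed = 11L, survey_fraction = 0.5, ...) {
  sim_params(n_persons = n, seed = seed, survey_fraction = survey_fraction, ...)
}
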