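## Synthetic registry and survey generator.
##
## Mortality follows a Gompertz background hazard plus a constant
## stage-specific excess hazard acting from diagnosis:
##   mu(a) = alpha * exp(beta * a) + excess(stage),  a = attained age in years.
## This is the simplest survival model with a closed-form cumulative hazard,
## so every downstream life-table quantity has an analytic oracle.

# Cumulative hazard over [a0, a0 + t] for attained-age Gompertz + constant excess.
gompertz_cumhaz <- function(alpha, beta, excess, a0, t) {
  if (beta == 0) return((alpha + excess) * t)
  (alpha / beta) * (exp(beta * (a0 + t)) - exp(beta * a0)) + excess * t
}

gompertz_hazard <- function(alpha, beta, excess, a) {
  alpha * exp(beta * a) + excess
}

# Vectorised inversion sampler: solves H(t) = e for t by Newton iteration on
# the (convex, increasing) cumulative hazard; e is a unit-exponential draw.
sample_death_times <- function(alpha, beta, excess, a0, e) {
  n <- length(e)
  excess <- rep_len(excess, n)
  a0 <- rep_len(a0, n)
  mu0 <- gompertz_hazard(alpha, beta, excess, a0)
  if (any(mu0 <= 0 & alpha <= 0))
    stop("total hazard must be positive to sample death times", call. = FALSE)
  t <- e / pmax(mu0, 1e-12)
  for (i in seq_len(200L)) {
    H <- if (beta == 0) (alpha + excess) * t else
      (alpha / beta) * (exp(beta * (a0 + t)) - exp(beta * a0)) + excess * t
    f <- H - e
    if (all(abs(f) < 1e-12)) break
    mu <- gompertz_hazard(alpha, beta, excess, a0 + t)
    t <- pmax(0, t - f / pmax(mu, 1e-300))
  }
  t
}

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * stream) %% 2147483647)
}

#' Simulation parameters for the synthetic registry cohort
#'
#' Defaults emulate a population-based colorectal-cancer survivor cohort:
#' roughly fifteen thousand survivors alive in a five-year observation window,
#' 53\% male, a stage mix dominated by stages I-II, stage-dependent excess
#' mortality on top of Gompertz background ageing, and a cross-sectional
#' quality-of-life survey of a random subsample with age-, stage- and
#' comorbidity-dependent prevalence of poor self-rated health and walking
#' disability.
#'
#' @param n_persons Number of registry records to generate.
#' @param seed Integer seed; all substreams are derived from it.
#' @param window_start,window_end Observation window (Dates or ISO strings).
#' @param background_alpha,background_beta Gompertz background hazard:
#'   `alpha * exp(beta * age)` per year, `age` in years from birth.
#' @param stage_probs Probabilities of recorded stages I-IV (sums to 1).
#' @param stage_unknown_prob Probability the recorded stage is masked to
#'   `"unknown"` (the true stage still drives survival).
#' @param stage_excess_hazard Constant excess hazard per year for stages I-IV,
#'   acting from diagnosis onward.
#' @param sex_ratio Probability male.
#' @param site_prob_colon Probability the site is colon (vs rectum).
#' @param treatment_probs Probabilities of the four treatment groups.
#' @param comorbidity_prob Probability of >= 1 comorbidity (among known).
#' @param comorbidity_unknown_prob Probability comorbidity status is unknown.
#' @param ses_probs Probabilities of high/middle/low SES among persons with an
#'   ordinary SES class (sums to 1).
#' @param ses_institutionalized_prob,ses_unknown_prob Probabilities of the
#'   institutionalized and unknown SES categories.
#' @param diagnosis_start,diagnosis_end Diagnosis dates drawn uniformly here.
#' @param diagnosis_age_mean,diagnosis_age_sd Normal age-at-diagnosis model,
#'   truncated to `diagnosis_age_range`.
#' @param diagnosis_age_range Lower/upper truncation for age at diagnosis.
#' @param followup_end Administrative end of follow-up (censoring date).
#' @param survey_date Date of the cross-sectional survey.
#' @param survey_fraction Probability an eligible (alive) survivor is sampled.
#' @param response_coefs Logistic response model `c(intercept, poor_offset)`:
#'   log-odds of returning the questionnaire, shifted for persons in the poor
#'   health state (allows health-dependent nonresponse).
#' @param poor_health_coefs Logistic model for the poor/fair health state:
#'   `c(intercept, age, stageII, stageIII, stageIV, comorbidity)` with age
#'   centred at 70 years; stage I is the reference.
#' @param disability_coefs Same structure for the walking-limitation state.
#' @param item_missing_general,item_missing_walking Probability a returned
#'   questionnaire has the respective item missing.
#' @return An object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(n_persons = 14849L,
                       seed = 1L,
                       window_start = "2005-01-01",
                       window_end = "2009-12-31",
                       background_alpha = 2e-5,
                       background_beta = 0.095,
                       stage_probs = c(3884, 5284, 3659, 2022) / 14849,
                       stage_unknown_prob = 0.04,
                       stage_excess_hazard = c(0.035, 0.07, 0.14, 0.45),
                       sex_ratio = 0.53,
                       site_prob_colon = 0.65,
                       treatment_probs = c(0.596, 0.148, 0.201, 0.055),
                       comorbidity_prob = 0.63,
                       comorbidity_unknown_prob = 0.165,
                       ses_probs = c(0.322, 0.408, 0.270),
                       ses_institutionalized_prob = 0.041,
                       ses_unknown_prob = 0.035,
                       diagnosis_start = "1995-01-01",
                       diagnosis_end = "2009-12-31",
                       diagnosis_age_mean = 68,
                       diagnosis_age_sd = 11,
                       diagnosis_age_range = c(30, 95),
                       followup_end = window_end,
                       survey_date = "2009-07-01",
                       survey_fraction = 0.24,
                       response_coefs = c(1.6, -0.5),
                       poor_health_coefs = c(intercept = -1.9, age = 0.02,
                                             stageII = -0.25, stageIII = 0.10,
                                             stageIV = 1.75, comorbidity = 0.9),
                       disability_coefs = c(intercept = -1.6, age = 0.055,
                                            stageII = 0.18, stageIII = 0.48,
                                            stageIV = 1.42, comorbidity = 0.74),
                       item_missing_general = 0.07,
                       item_missing_walking = 0.12) {
  p <- list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    window_start = as_date_strict(window_start, "window_start"),
    window_end = as_date_strict(window_end, "window_end"),
    background_alpha = background_alpha, background_beta = background_beta,
    stage_probs = stage_probs,
    stage_unknown_prob = stage_unknown_prob,
    stage_excess_hazard = stage_excess_hazard,
    sex_ratio = sex_ratio, site_prob_colon = site_prob_colon,
    treatment_probs = treatment_probs,
    comorbidity_prob = comorbidity_prob,
    comorbidity_unknown_prob = comorbidity_unknown_prob,
    ses_probs = ses_probs,
    ses_institutionalized_prob = ses_institutionalized_prob,
    ses_unknown_prob = ses_unknown_prob,
    diagnosis_start = as_date_strict(diagnosis_start, "diagnosis_start"),
    diagnosis_end = as_date_strict(diagnosis_end, "diagnosis_end"),
    diagnosis_age_mean = diagnosis_age_mean,
    diagnosis_age_sd = diagnosis_age_sd,
    diagnosis_age_range = diagnosis_age_range,
    followup_end = as_date_strict(followup_end, "followup_end"),
    survey_date = as_date_strict(survey_date, "survey_date"),
    survey_fraction = survey_fraction,
    response_coefs = response_coefs,
    poor_health_coefs = poor_health_coefs,
    disability_coefs = disability_coefs,
    item_missing_general = item_missing_general,
    item_missing_walking = item_missing_walking)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_persons < 0) stop("'n_persons' must be >= 0", call. = FALSE)
  if (!(p$window_start < p$window_end))
    stop("'window_start' must precede 'window_end'", call. = FALSE)
  if (!(p$diagnosis_start <= p$diagnosis_end))
    stop("'diagnosis_start' must not exceed 'diagnosis_end'", call. = FALSE)
  if (p$background_alpha < 0) stop("'background_alpha' must be >= 0", call. = FALSE)
  if (any(p$stage_excess_hazard < 0))
    stop("'stage_excess_hazard' must be >= 0", call. = FALSE)
  check_simplex(p$stage_probs, "stage_probs", 4L)
  check_simplex(p$treatment_probs, "treatment_probs", 4L)
  check_simplex(p$ses_probs, "ses_probs", 3L)
  check_prob(p$sex_ratio, "sex_ratio")
  check_prob(p$site_prob_colon, "site_prob_colon")
  check_prob(p$comorbidity_prob, "comorbidity_prob")
  check_prob(p$comorbidity_unknown_prob, "comorbidity_unknown_prob")
  check_prob(p$stage_unknown_prob, "stage_unknown_prob")
  check_prob(p$ses_institutionalized_prob, "ses_institutionalized_prob")
  check_prob(p$ses_unknown_prob, "ses_unknown_prob")
  check_prob(p$survey_fraction, "survey_fraction")
  check_prob(p$item_missing_general, "item_missing_general")
  check_prob(p$item_missing_walking, "item_missing_walking")
  for (nm in c("poor_health_coefs", "disability_coefs"))
    if (length(p[[nm]]) != 6L)
      stop(sprintf("'%s' must have 6 coefficients (intercept, age, stage II-IV, comorbidity)", nm),
           call. = FALSE)
  if (length(p$response_coefs) != 2L)
    stop("'response_coefs' must be c(intercept, poor_offset)", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic registry simulation parameters\n")
  cat(sprintf("  persons: %d, seed: %d\n", x$n_persons, x$seed))
  cat(sprintf("  window:  %s .. %s\n", x$window_start, x$window_end))
  cat(sprintf("  background Gompertz: alpha = %g/yr, beta = %g/yr\n",
              x$background_alpha, x$background_beta))
  cat(sprintf("  stage excess (I-IV): %s /yr\n",
              paste(x$stage_excess_hazard, collapse = ", ")))
  invisible(x)
}

empty_cohort <- function() {
  data.frame(person_id = character(), sex = character(),
             birth_date = as.Date(character()),
             diagnosis_date = as.Date(character()),
             site = character(), stage = character(), treatment = character(),
             comorbidity = character(), ses = character(),
             vital_status = character(),
             exit_date = as.Date(character()),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic registry cohort
#'
#' Draws `n_persons` survivor records. Age at diagnosis is truncated normal,
#' diagnosis dates uniform, and the death time from diagnosis is sampled by
#' inverting the cumulative hazard of the Gompertz-plus-excess model. Deaths
#' after `followup_end` are administratively censored. Persons dying before
#' the observation window are still emitted; window filtering is
#' [select_alive_in_window()]'s job.
#'
#' @param params A [sim_params()] object.
#' @return A data.frame of person records (one row per person) with columns
#'   `person_id, sex, birth_date, diagnosis_date, site, stage, treatment,
#'   comorbidity, ses, vital_status, exit_date`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  n <- params$n_persons
  if (n == 0L) return(empty_cohort())
  set.seed(derive_seed(params$seed, 1L))

  sex <- ifelse(stats::runif(n) < params$sex_ratio, "male", "female")
  true_stage_idx <- sample.int(4L, n, replace = TRUE, prob = params$stage_probs)
  stage <- c("I", "II", "III", "IV")[true_stage_idx]
  stage[stats::runif(n) < params$stage_unknown_prob] <- "unknown"
  site <- ifelse(stats::runif(n) < params$site_prob_colon, "colon", "rectum")
  treatment <- TREATMENT_LEVELS[sample.int(4L, n, replace = TRUE,
                                           prob = params$treatment_probs)]
  comorbidity <- ifelse(stats::runif(n) < params$comorbidity_prob, "1plus", "0")
  comorbidity[stats::runif(n) < params$comorbidity_unknown_prob] <- "unknown"
  u_ses <- stats::runif(n)
  ses <- rep("high", n)
  p_inst <- params$ses_institutionalized_prob
  p_unk <- params$ses_unknown_prob
  ordinary <- u_ses >= p_inst + p_unk
  ses[u_ses < p_inst] <- "institutionalized"
  ses[u_ses >= p_inst & u_ses < p_inst + p_unk] <- "unknown"
  ses[ordinary] <- SES_LEVELS[1:3][sample.int(3L, sum(ordinary), replace = TRUE,
                                              prob = params$ses_probs)]

  # truncated-normal age at diagnosis via inverse CDF
  rng <- params$diagnosis_age_range
  plo <- stats::pnorm(rng[1], params$diagnosis_age_mean, params$diagnosis_age_sd)
  phi <- stats::pnorm(rng[2], params$diagnosis_age_mean, params$diagnosis_age_sd)
  age_dx <- stats::qnorm(plo + stats::runif(n) * (phi - plo),
                         params$diagnosis_age_mean, params$diagnosis_age_sd)

  dx_num <- as.numeric(params$diagnosis_start) +
    stats::runif(n) * (as.numeric(params$diagnosis_end) - as.numeric(params$diagnosis_start))
  diagnosis_date <- as.Date(round(dx_num), origin = "1970-01-01")
  birth_date <- as.Date(round(as.numeric(diagnosis_date) - age_dx * YEAR_DAYS),
                        origin = "1970-01-01")
  age_dx <- years_between(birth_date, diagnosis_date)

  excess <- params$stage_excess_hazard[true_stage_idx]
  t_death <- sample_death_times(params$background_alpha, params$background_beta,
                                excess, age_dx, stats::rexp(n))
  death_num <- as.numeric(diagnosis_date) + t_death * YEAR_DAYS
  end_num <- as.numeric(params$followup_end)
  dead <- death_num <= end_num
  exit_date <- as.Date(ifelse(dead, pmax(round(death_num), as.numeric(diagnosis_date)),
                              end_num), origin = "1970-01-01")

  data.frame(person_id = sprintf("p%06d", seq_len(n)),
             sex = sex, birth_date = birth_date, diagnosis_date = diagnosis_date,
             site = site, stage = stage, treatment = treatment,
             comorbidity = comorbidity, ses = ses,
             vital_status = ifelse(dead, "dead", "censored"),
             exit_date = exit_date, stringsAsFactors = FALSE)
}

# Linear predictor of the generating health-state models: age centred at 70,
# stage I (or unknown) reference, comorbidity "1plus" indicator.
health_linpred <- function(coefs, age, stage, comorbidity) {
  off <- numeric(length(age))
  off[stage == "II"] <- coefs[3]
  off[stage == "III"] <- coefs[4]
  off[stage == "IV"] <- coefs[5]
  coefs[1] + coefs[2] * (age - 70) + off + coefs[6] * (comorbidity == "1plus")
}

#' Generate a synthetic cross-sectional quality-of-life survey
#'
#' Only persons alive (and already diagnosed) on the survey date are eligible.
#' Eligible persons are sampled with probability `survey_fraction`; whether a
#' sampled person responds follows the logistic response model, whose offset
#' for persons in the poor-health state allows health-dependent nonresponse.
#' Among respondents, the probability of answering fair-or-poor on the general
#' health item equals the poor-health logistic model evaluated at the person's
#' age, recorded stage, and comorbidity; likewise for the walking item and the
#' disability model. Within the good mass the three favourable levels are
#' equiprobable, as are the two adverse levels within the poor mass: only the
#' dichotomy matters downstream.
#'
#' @param cohort A cohort data.frame from [generate_cohort()] (nonempty).
#' @param params The same [sim_params()] object.
#' @return Data.frame with columns `person_id, survey_date,
#'   general_health_item, walking_item`, one row per respondent.
#' @export
generate_survey <- function(cohort, params) {
  stopifnot(inherits(params, "sim_params"))
  if (nrow(cohort) == 0L) stop("'cohort' must be nonempty", call. = FALSE)
  set.seed(derive_seed(params$seed, 2L))
  s <- params$survey_date
  alive <- (cohort$vital_status == "censored" & cohort$exit_date >= s) |
    (cohort$vital_status == "dead" & cohort$exit_date > s)
  eligible <- cohort[alive & cohort$diagnosis_date <= s, , drop = FALSE]
  empty <- data.frame(person_id = character(), survey_date = as.Date(character()),
                      general_health_item = character(), walking_item = character(),
                      stringsAsFactors = FALSE)
  if (nrow(eligible) == 0L) return(empty)
  sampled <- eligible[stats::runif(nrow(eligible)) < params$survey_fraction, ,
                      drop = FALSE]
  if (nrow(sampled) == 0L) return(empty)
  m <- nrow(sampled)
  age <- years_between(sampled$birth_date, s)

  p_poor <- stats::plogis(health_linpred(params$poor_health_coefs, age,
                                         sampled$stage, sampled$comorbidity))
  poor <- stats::runif(m) < p_poor
  p_dis <- stats::plogis(health_linpred(params$disability_coefs, age,
                                        sampled$stage, sampled$comorbidity))
  disabled <- stats::runif(m) < p_dis
  p_resp <- stats::plogis(params$response_coefs[1] + params$response_coefs[2] * poor)
  responded <- stats::runif(m) < p_resp

  gh <- ifelse(poor, c("fair", "poor")[1L + (stats::runif(m) < 0.5)],
               c("excellent", "very_good", "good")[sample.int(3L, m, replace = TRUE)])
  walk <- ifelse(disabled,
                 c("very_limited", "little_limited")[1L + (stats::runif(m) < 0.5)],
                 "not_limited")
  gh[stats::runif(m) < params$item_missing_general] <- "missing"
  walk[stats::runif(m) < params$item_missing_walking] <- "missing"

  out <- data.frame(person_id = sampled$person_id,
                    survey_date = rep(s, m),
                    general_health_item = gh, walking_item = walk,
                    stringsAsFactors = FALSE)
  out[responded, , drop = FALSE]
}

#' Remaining life expectancy under the generating hazard
#'
#' Closed-form oracle for parameter-recovery tests: integrates the survivor
#' function `exp(-H(t))` of the Gompertz-plus-constant-excess hazard from the
#' given age by adaptive quadrature, truncated where survivorship drops below
#' 1e-12.
#'
#' @param alpha,beta Gompertz background parameters (rate/yr at age 0;
#'   log-slope per year of age).
#' @param excess Constant additive excess hazard per year.
#' @param age Age (years) from which remaining life expectancy is taken.
#' @return Remaining life expectancy in years.
#' @export
analytic_life_expectancy <- function(alpha, beta, excess = 0, age = 50) {
  if (alpha < 0 || excess < 0) stop("hazard parameters must be >= 0", call. = FALSE)
  if (alpha == 0 && excess == 0) stop("total hazard is identically zero", call. = FALSE)
  surv <- function(t) exp(-gompertz_cumhaz(alpha, beta, excess, age, t))
  cut <- -log(1e-12)
  upper <- 1
  while (gompertz_cumhaz(alpha, beta, excess, age, upper) < cut && upper < 1e8)
    upper <- upper * 2
  horizon <- stats::uniroot(function(t) gompertz_cumhaz(alpha, beta, excess, age, t) - cut,
                            c(0, upper), tol = 1e-10)$root
  q <- stats::integrate(surv, 0, horizon, rel.tol = 1e-10, subdivisions = 2000L)
  if (q$message != "OK")
    stop("quadrature did not converge: ", q$message, call. = FALSE)
  q$value
}
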