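## Sullivan-method health expectancy: weight life-table person-years by the
## age-specific probability of being in the healthy (or non-disabled) state.
##
##   HLE_x = ( sum_{y >= x} (1 - pi_y) L_y ) / l_x
##
## with pi_y the cross-sectional prevalence of the adverse state. The default
## standard error carries only the binomial prevalence variance
##   Var(HLE_x) = sum_{y >= x} L_y^2 pi_y (1 - pi_y) / n_y / l_x^2 ;
## the mortality-variance term of the Chiang extension can be added.

#' Sullivan health expectancy at one age
#'
#' @param lt A [build_life_table()] result.
#' @param prev A [prevalence_by_age()] result on the same grid.
#' @param age Reporting age; must be a grid boundary.
#' @param mortality_variance Add the Chiang mortality-variance component to
#'   the standard error (requires the exposure table used for the life table
#'   via `exposure`). Off by default: with a large registry and a small
#'   survey the prevalence term dominates.
#' @param exposure Exposure table (deaths, person_years) when
#'   `mortality_variance = TRUE`.
#' @return One-row data.frame of class `health_expectancy`: `age, LE,
#'   state_free_LE, prop, se, ci_low, ci_high` where `state_free_LE` is HLE or
#'   DFLE according to the outcome carried by `prev`.
#' @export
sullivan_expectancy <- function(lt, prev, age, mortality_variance = FALSE,
                                exposure = NULL) {
  stopifnot(inherits(lt, "life_table"), inherits(prev, "prevalence_table"))
  if (nrow(lt) != nrow(prev) ||
      !isTRUE(all.equal(attr(lt, "grid")$lower, attr(prev, "grid")$lower)))
    stop("life table and prevalence table must share the same age grid",
         call. = FALSE)
  i <- match(age, lt$age)
  if (is.na(i)) stop(sprintf("age %g is not a grid boundary", age), call. = FALSE)
  sel <- seq(i, nrow(lt))
  pi <- prev$pi[sel]
  if (anyNA(pi))
    stop("prevalence missing in cell(s) ",
         paste(prev$age_group[sel][is.na(pi)], collapse = ", "),
         "; enable borrowing in prevalence_by_age()", call. = FALSE)
  lx <- lt$l[i]
  L <- lt$L[sel]
  hle <- sum((1 - pi) * L) / lx
  le <- lt$e[i]
  var_prev <- sum(L^2 * pi * (1 - pi) / pmax(prev$n[sel], 1)) / lx^2
  var_total <- var_prev
  if (mortality_variance) {
    if (is.null(exposure))
      stop("'exposure' is required for the mortality-variance component",
           call. = FALSE)
    var_total <- var_prev + chiang_mortality_variance(lt, prev, exposure, i)
  }
  se <- sqrt(var_total)
  out <- data.frame(age = age, LE = le, state_free_LE = hle,
                    prop = 100 * hle / le, se = se,
                    ci_low = hle - 1.96 * se, ci_high = hle + 1.96 * se)
  class(out) <- c("health_expectancy", "data.frame")
  attr(out, "outcome") <- attr(prev, "outcome")
  out
}

# Chiang-style mortality component of the Sullivan variance: the sampling
# variance of q_y (binomial on the deaths) propagated through the healthy
# person-years, the direct analogue of Chiang's life-expectancy variance.
# Config-gated extension of the default prevalence-only SE.
chiang_mortality_variance <- function(lt, prev, exposure, i) {
  k <- nrow(lt)
  q <- lt$q
  var_q <- ifelse(exposure$deaths > 0, q^2 * (1 - q) / exposure$deaths, 0)
  # healthy expectancy per survivor at each exact age; 0 beyond the table
  hLy <- (1 - prev$pi) * lt$L
  h_e <- rev(cumsum(rev(hLy))) / pmax(lt$l, 1e-300)
  h_next <- c(h_e[-1L], 0)
  sens <- (1 - prev$pi) * lt$a + h_next   # d(HLE)/d(q_y) sensitivity, per l_y
  closed <- seq_len(k - 1L)
  sel <- closed[closed >= i]
  sum(lt$l[sel]^2 * sens[sel]^2 * var_q[sel]) / lt$l[i]^2
}

#' Percent of remaining life spent in the favourable state
#'
#' @param hle Health (or disability-free) expectancy in years.
#' @param le Total life expectancy in years; must satisfy `0 <= hle <= le`,
#'   `le > 0`.
#' @param digits Rounding of the reported percentage (integer percent by
#'   default, the usual reporting convention).
#' @return `100 * hle / le`, rounded.
#' @export
proportion_in_state <- function(hle, le, digits = 0) {
  if (any(le <= 0)) stop("'le' must be positive", call. = FALSE)
  if (any(hle < 0) || any(hle > le + 1e-12))
    stop("'hle' must lie in [0, le]", call. = FALSE)
  round(100 * hle / le, digits)
}

#' Stratified Sullivan analysis
#'
#' Runs person-time splitting, life-table construction, prevalence estimation
#' and the Sullivan combination within each level of each requested stratum,
#' for both outcomes, at the given reporting ages. Strata with no deaths in
#' any cell raise an error naming the stratum; strata with few deaths or few
#' respondents are flagged, not dropped.
#'
#' @param cohort Selected cohort data.frame.
#' @param survey Survey data.frame.
#' @param filter A [cohort_filter()].
#' @param grid An [age_grid()].
#' @param strata Character vector of person covariates to stratify on, from
#'   `sex, ses, stage, comorbidity, followup, site, treatment`; `character(0)`
#'   gives the single overall row (stratum `"all"`). Stage-stratified runs
#'   drop unknown-stage records; SES-stratified tables report only
#'   high/middle/low.
#' @param ages Reporting ages (grid boundaries); default 50, 65 and 80.
#' @param min_deaths,min_resp Flag thresholds for sparse strata.
#' @return Data.frame with one row per stratum level x age: `stratum, level,
#'   age, LE, HLE, DFLE, prop_HLE, prop_DFLE, se_HLE, se_DFLE, ci_low_HLE,
#'   ci_high_HLE, n_deaths, n_resp, sparse`.
#' @export
stratified_sullivan <- function(cohort, survey, filter, grid,
                                strata = character(), ages = c(50, 65, 80),
                                min_deaths = 50L, min_resp = 30L) {
  stopifnot(inherits(filter, "cohort_filter"), inherits(grid, "age_grid"))
  stratum_values <- function(var) {
    switch(var,
           followup = assign_followup_class(cohort, filter),
           cohort[[var]])
  }
  run_level <- function(svar, level, rows) {
    sub <- cohort[rows, , drop = FALSE]
    expo <- aggregate_exposure(sub, filter, grid)
    if (sum(expo$deaths) == 0L)
      stop(sprintf("stratum %s = %s has zero deaths in every age group", svar, level),
           call. = FALSE)
    lt <- build_life_table(death_rates(expo), grid)
    in_level <- survey$person_id %in% sub$person_id
    hp <- suppressWarnings(
      prevalence_by_age(survey, cohort, grid, "poor_health", subset = in_level))
    dp <- suppressWarnings(
      prevalence_by_age(survey, cohort, grid, "disability", subset = in_level))
    res <- lapply(ages, function(a) {
      # extreme strata can extinguish the abridged table before a late
      # reporting age (q capped at 1); flag such cells instead of aborting
      if (life_expectancy(lt, a) <= 0 || lt$l[match(a, lt$age)] <= 0)
        return(data.frame(stratum = svar, level = level, age = a,
                          LE = NA_real_, HLE = NA_real_, DFLE = NA_real_,
                          prop_HLE = NA_real_, prop_DFLE = NA_real_,
                          se_HLE = NA_real_, se_DFLE = NA_real_,
                          ci_low_HLE = NA_real_, ci_high_HLE = NA_real_,
                          n_deaths = sum(expo$deaths), n_resp = sum(in_level),
                          sparse = TRUE, stringsAsFactors = FALSE))
      h <- sullivan_expectancy(lt, hp, a)
      d <- sullivan_expectancy(lt, dp, a)
      data.frame(stratum = svar, level = level, age = a,
                 LE = h$LE, HLE = h$state_free_LE, DFLE = d$state_free_LE,
                 prop_HLE = proportion_in_state(h$state_free_LE, h$LE),
                 prop_DFLE = proportion_in_state(d$state_free_LE, d$LE),
                 se_HLE = h$se, se_DFLE = d$se,
                 ci_low_HLE = h$ci_low, ci_high_HLE = h$ci_high,
                 n_deaths = sum(expo$deaths),
                 n_resp = sum(in_level),
                 sparse = sum(expo$deaths) < min_deaths || sum(in_level) < min_resp,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  if (length(strata) == 0L)
    return(run_level("all", "all", seq_len(nrow(cohort))))
  out <- list()
  for (svar in strata) {
    vals <- stratum_values(svar)
    if (is.null(vals)) stop("unknown stratum variable: ", svar, call. = FALSE)
    levels_keep <- setdiff(unique(vals), switch(svar,
      stage = "unknown", ses = c("institutionalized", "unknown"), character()))
    for (lev in sort(levels_keep))
      out[[paste(svar, lev)]] <- run_level(svar, lev, which(vals == lev))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
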