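## SF-36 item dichotomization and age-specific prevalence tables.

#' Dichotomize the SF-36 general-health item
#'
#' Excellent, very good and good collapse to `good`; fair and poor to `poor`;
#' `missing` stays missing and is excluded from prevalence denominators.
#'
#' @param level Character vector of item levels.
#' @return Character vector in `{good, poor, missing}`.
#' @export
dichotomize_general_health <- function(level) {
  bad <- !(level %in% GH_LEVELS)
  if (any(bad))
    stop("unknown general-health token(s): ",
         paste(unique(level[bad]), collapse = ", "), call. = FALSE)
  out <- rep("missing", length(level))
  out[level %in% c("excellent", "very_good", "good")] <- "good"
  out[level %in% c("fair", "poor")] <- "poor"
  out
}

#' Dichotomize the SF-36 walking-limitation item
#'
#' Functional limitation is assigned to "very much limited" and "a little bit
#' limited"; only "not limited" counts as free of limitation.
#'
#' @param level Character vector of item levels.
#' @return Character vector in `{limited, not_limited, missing}`.
#' @export
dichotomize_walking <- function(level) {
  bad <- !(level %in% WALK_LEVELS)
  if (any(bad))
    stop("unknown walking-item token(s): ",
         paste(unique(level[bad]), collapse = ", "), call. = FALSE)
  out <- rep("missing", length(level))
  out[level %in% c("very_limited", "little_limited")] <- "limited"
  out[level == "not_limited"] <- "not_limited"
  out
}

#' Age-specific prevalence of poor health or walking disability
#'
#' Joins survey records to person records, indexes each respondent by age at
#' survey on the life-table grid, and computes the proportion in the adverse
#' state with its binomial standard error. Respondents with a missing outcome
#' are dropped from both numerator and denominator; respondents below the grid
#' floor are excluded. Cells without respondents are flagged and, under the
#' default borrowing rule, filled with the nearest non-empty younger cell's
#' proportion (falling back to the nearest older cell at the grid floor) so
#' that sparse old-age cells — the open interval especially — do not truncate
#' the Sullivan sum.
#'
#' @param survey Survey data.frame (`person_id, survey_date, ...`).
#' @param cohort Cohort data.frame supplying `birth_date` and covariates.
#' @param grid An [age_grid()] shared with the life table.
#' @param outcome `"poor_health"` (general-health item) or `"disability"`
#'   (walking item).
#' @param subset Optional logical vector over `survey` rows restricting to a
#'   stratum.
#' @param borrow `"nearest"` (default) or `"none"` (empty cells keep `NA`).
#' @return Data.frame of class `prevalence_table`: `age_group, n, k, pi, se,
#'   borrowed` with rows aligned one-to-one with the grid.
#' @export
prevalence_by_age <- function(survey, cohort, grid,
                              outcome = c("poor_health", "disability"),
                              subset = NULL,
                              borrow = c("nearest", "none")) {
  outcome <- match.arg(outcome)
  borrow <- match.arg(borrow)
  stopifnot(inherits(grid, "age_grid"))
  if (!is.null(subset)) survey <- survey[subset, , drop = FALSE]
  idx <- match(survey$person_id, cohort$person_id)
  if (anyNA(idx))
    stop("survey person_id(s) without a matching person record: ",
         paste(utils::head(unique(survey$person_id[is.na(idx)]), 5L),
               collapse = ", "), call. = FALSE)
  age <- years_between(cohort$birth_date[idx], survey$survey_date)
  state <- if (outcome == "poor_health")
    dichotomize_general_health(survey$general_health_item)
  else dichotomize_walking(survey$walking_item)
  adverse <- if (outcome == "poor_health") "poor" else "limited"
  keep <- state != "missing" & age >= grid$lower[1L]
  cell <- findInterval(age[keep], grid$lower)
  k_ <- length(grid$lower)
  n <- tabulate(cell, nbins = k_)
  k <- tabulate(cell[state[keep] == adverse], nbins = k_)
  pi <- ifelse(n > 0, k / n, NA_real_)
  borrowed <- rep(FALSE, k_)
  if (borrow == "nearest" && any(n == 0) && any(n > 0)) {
    filled <- which(n > 0)
    for (i in which(n == 0)) {
      younger <- filled[filled < i]
      donor <- if (length(younger)) max(younger) else min(filled)
      pi[i] <- pi[donor]
      n[i] <- n[donor]  # donor denominator carries into the variance term
      k[i] <- k[donor]
      borrowed[i] <- TRUE
    }
    warning(sprintf("%d empty prevalence cell(s) filled from the nearest non-empty cell",
                    sum(borrowed)), call. = FALSE)
  }
  se <- ifelse(n > 0, sqrt(pi * (1 - pi) / n), NA_real_)
  out <- data.frame(age_group = grid$labels, n = n, k = k, pi = pi, se = se,
                    borrowed = borrowed, stringsAsFactors = FALSE)
  class(out) <- c("prevalence_table", "data.frame")
  attr(out, "grid") <- grid
  attr(out, "outcome") <- outcome
  out
}
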