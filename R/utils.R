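## Shared helpers: continuous-time date arithmetic and closed vocabularies.

# Mean Gregorian year length; all ages are exact real-valued year fractions.
YEAR_DAYS <- 365.2425

#' Age in exact years between two dates
#'
#' Ages and durations are real-valued year fractions computed on a
#' 365.2425-day year, so age-group boundaries are crossed at the exact
#' birthday instant rather than at calendar-day granularity.
#'
#' @param from,to `Date` vectors (recycled).
#' @return Numeric vector of years elapsed from `from` to `to`.
#' @export
years_between <- function(from, to) {
  (as.numeric(to) - as.numeric(from)) / YEAR_DAYS
}

# Instant (in days since epoch, possibly fractional) at which a person born
# on `birth` attains exact age `age` in years.
date_at_age <- function(birth, age) {
  as.numeric(birth) + age * YEAR_DAYS
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))
    stop(sprintf("unparseable %s at position(s) %s (expected ISO-8601 YYYY-MM-DD)",
                 what, paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

## Closed category vocabularies (lowercase tokens, as written to CSV).
SEX_LEVELS       <- c("male", "female")
SITE_LEVELS      <- c("colon", "rectum")
STAGE_LEVELS     <- c("I", "II", "III", "IV", "unknown")
TREATMENT_LEVELS <- c("surgery_only", "surgery_chemo", "surgery_radio_chemo", "other")
COMORB_LEVELS    <- c("0", "1plus", "unknown")
SES_LEVELS       <- c("high", "middle", "low", "institutionalized", "unknown")
VITAL_LEVELS     <- c("dead", "censored")
GH_LEVELS        <- c("excellent", "very_good", "good", "fair", "poor", "missing")
WALK_LEVELS      <- c("very_limited", "little_limited", "not_limited", "missing")

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_simplex <- function(x, name, k, tol = 1e-9) {
  check_prob(x, name)
  if (length(x) != k)
    stop(sprintf("'%s' must have length %d", name, k), call. = FALSE)
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("'%s' must sum to 1 (got %.12f)", name, sum(x)), call. = FALSE)
  invisible(x)
}
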