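## Reading, validating and filtering registry and survey tables.

COHORT_COLUMNS <- c("person_id", "sex", "birth_date", "diagnosis_date", "site",
                    "stage", "treatment", "comorbidity", "ses", "vital_status",
                    "exit_date")
SURVEY_COLUMNS <- c("person_id", "survey_date", "general_health_item",
                    "walking_item")

# Documented alias table: tokens accepted on input beyond the canonical
# lowercase vocabulary. Stage digits follow the usual registry coding.
STAGE_ALIASES <- stats::setNames(
  c("I", "II", "III", "IV", "I", "II", "III", "IV", "unknown", "unknown"),
  c("1", "2", "3", "4", "i", "ii", "iii", "iv", "x", ""))
SEX_ALIASES <- c(m = "male", f = "female")
GH_ALIASES <- stats::setNames(
  c("excellent", "very_good", "good", "fair", "poor", "very_good", "missing"),
  c("1", "2", "3", "4", "5", "very good", ""))
WALK_ALIASES <- stats::setNames(
  c("very_limited", "little_limited", "not_limited", "missing"),
  c("1", "2", "3", ""))

# Map raw tokens onto a closed vocabulary. Tokens outside vocabulary and alias
# table fall back to "unknown"/"missing" when the vocabulary has such a level
# (with a warning), otherwise raise a row-indexed error.
map_tokens <- function(x, levels, aliases = NULL, column = "column") {
  x <- trimws(tolower(as.character(x)))
  x[is.na(x)] <- ""
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- aliases[x[hit]]
  }
  # stages are stored in roman upper case
  if (identical(levels, STAGE_LEVELS)) {
    roman <- toupper(x) %in% c("I", "II", "III", "IV")
    x[roman] <- toupper(x[roman])
  }
  bad <- !(x %in% levels)
  if (any(bad)) {
    fallback <- intersect(c("unknown", "missing"), levels)
    if (length(fallback)) {
      warning(sprintf("%d unrecognised '%s' token(s) (e.g. %s) mapped to '%s'",
                      sum(bad), column,
                      paste(utils::head(unique(x[bad]), 3L), collapse = ", "),
                      fallback[1]), call. = FALSE)
      x[bad] <- fallback[1]
    } else {
      stop(sprintf("invalid '%s' token(s) in row(s) %s: %s", column,
                   paste(utils::head(which(bad), 5L), collapse = ", "),
                   paste(utils::head(unique(x[bad]), 3L), collapse = ", ")),
           call. = FALSE)
    }
  }
  x
}

#' Read a registry cohort CSV
#'
#' Expects exactly the person-record schema written by [write_cohort()]:
#' ISO-8601 dates and lowercase category tokens. A documented alias table is
#' applied (e.g. stage `"2"` is read as stage `II`); tokens that remain
#' unrecognised are mapped to the `unknown` level with a warning where the
#' vocabulary has one. Rows violating the date invariants (diagnosis before
#' birth, exit before diagnosis) raise an error listing the row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  raw <- raw[COHORT_COLUMNS]
  out <- data.frame(person_id = raw$person_id,
                    sex = map_tokens(raw$sex, SEX_LEVELS, SEX_ALIASES, "sex"),
                    birth_date = as_date_strict(raw$birth_date, "birth_date"),
                    diagnosis_date = as_date_strict(raw$diagnosis_date, "diagnosis_date"),
                    site = map_tokens(raw$site, SITE_LEVELS, NULL, "site"),
                    stage = map_tokens(raw$stage, STAGE_LEVELS, STAGE_ALIASES, "stage"),
                    treatment = map_tokens(raw$treatment, TREATMENT_LEVELS, NULL, "treatment"),
                    comorbidity = map_tokens(raw$comorbidity, COMORB_LEVELS, NULL, "comorbidity"),
                    ses = map_tokens(raw$ses, SES_LEVELS, NULL, "ses"),
                    vital_status = map_tokens(raw$vital_status, VITAL_LEVELS, NULL, "vital_status"),
                    exit_date = as_date_strict(raw$exit_date, "exit_date"),
                    stringsAsFactors = FALSE)
  validate_cohort(out)
  out
}

validate_cohort <- function(cohort) {
  bad_dx <- which(cohort$diagnosis_date < cohort$birth_date)
  bad_exit <- which(cohort$exit_date < cohort$diagnosis_date)
  if (length(bad_dx))
    stop("diagnosis_date precedes birth_date in row(s): ",
         paste(utils::head(bad_dx, 10L), collapse = ", "), call. = FALSE)
  if (length(bad_exit))
    stop("exit_date precedes diagnosis_date in row(s): ",
         paste(utils::head(bad_exit, 10L), collapse = ", "), call. = FALSE)
  invisible(cohort)
}

#' @rdname read_cohort
#' @param cohort,survey Data frames to write.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(COHORT_COLUMNS %in% names(cohort)))
  utils::write.csv(cohort[COHORT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(SURVEY_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data.frame(person_id = raw$person_id,
             survey_date = as_date_strict(raw$survey_date, "survey_date"),
             general_health_item = map_tokens(raw$general_health_item, GH_LEVELS,
                                              GH_ALIASES, "general_health_item"),
             walking_item = map_tokens(raw$walking_item, WALK_LEVELS,
                                       WALK_ALIASES, "walking_item"),
             stringsAsFactors = FALSE)
}

#' @rdname read_cohort
#' @export
write_survey <- function(survey, path) {
  stopifnot(all(SURVEY_COLUMNS %in% names(survey)))
  utils::write.csv(survey[SURVEY_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort inclusion filter
#'
#' Encodes the cohort-inclusion rules: an observation window, a minimum
#' attained age while alive inside the window, and the cut splitting short
#' from long follow-up since diagnosis.
#'
#' @param window_start,window_end Observation window (Dates or ISO strings).
#' @param min_age_in_window Minimum age (years) a person must attain while
#'   alive inside the window; exposure also starts no earlier than this age.
#' @param followup_class_cut Years since diagnosis at or below which follow-up
#'   is classed `short` ("5 years or less"); above it, `long`.
#' @param strata Character vector of covariate names used by stratified runs.
#' @param alive_rule `"any_instant"` (default): alive at any instant inside
#'   the window qualifies. `"at_start"`: must be a diagnosed, living survivor
#'   on `window_start`.
#' @return Object of class `cohort_filter`.
#' @export
cohort_filter <- function(window_start = "2005-01-01",
                          window_end = "2009-12-31",
                          min_age_in_window = 50,
                          followup_class_cut = 5,
                          strata = character(),
                          alive_rule = c("any_instant", "at_start")) {
  ws <- as_date_strict(window_start, "window_start")
  we <- as_date_strict(window_end, "window_end")
  if (!(ws < we)) stop("'window_start' must precede 'window_end'", call. = FALSE)
  if (min_age_in_window < 0) stop("'min_age_in_window' must be >= 0", call. = FALSE)
  structure(list(window_start = ws, window_end = we,
                 min_age_in_window = min_age_in_window,
                 followup_class_cut = followup_class_cut,
                 strata = strata,
                 alive_rule = match.arg(alive_rule)),
            class = "cohort_filter")
}

#' @export
print.cohort_filter <- function(x, ...) {
  cat(sprintf("Cohort filter: window %s .. %s, min age %g, follow-up cut %g y (%s)\n",
              x$window_start, x$window_end, x$min_age_in_window,
              x$followup_class_cut, x$alive_rule))
  invisible(x)
}

#' Select survivors alive in the observation window
#'
#' Keeps persons who (i) are still under follow-up at `window_start`
#' (`exit_date >= window_start`), (ii) were diagnosed by `window_end`, and
#' (iii) attain `min_age_in_window` at some instant while alive inside the
#' window. Under `alive_rule = "at_start"` the person must additionally be a
#' diagnosed, living survivor on `window_start`. Idempotent; logs counts kept
#' and dropped.
#'
#' @param cohort A validated cohort data.frame.
#' @param filter A [cohort_filter()].
#' @return The subset of `cohort` meeting the inclusion rules.
#' @export
select_alive_in_window <- function(cohort, filter) {
  stopifnot(inherits(filter, "cohort_filter"))
  if (nrow(cohort) == 0L) return(cohort)
  ws <- as.numeric(filter$window_start)
  we <- as.numeric(filter$window_end)
  exit_n <- as.numeric(cohort$exit_date)
  dx_n <- as.numeric(cohort$diagnosis_date)
  # instant the person attains the minimum age
  bday_min <- date_at_age(cohort$birth_date, filter$min_age_in_window)
  keep <- exit_n >= ws & dx_n <= we & bday_min <= pmin(exit_n, we)
  if (filter$alive_rule == "at_start")
    keep <- keep & dx_n <= ws
  out <- cohort[keep, , drop = FALSE]
  message(sprintf("select_alive_in_window: kept %d of %d persons (%d dropped)",
                  nrow(out), nrow(cohort), nrow(cohort) - nrow(out)))
  if (nrow(out) == 0L) warning("no persons meet the inclusion rules", call. = FALSE)
  out
}

#' Classify follow-up as short or long
#'
#' Completed years from diagnosis to the person's entry into the observation
#' window (`max(window_start, diagnosis_date)`); `short` when at most
#' `followup_class_cut` years ("5 years or less"), else `long`. The class is
#' frozen at window entry.
#'
#' @param cohort Cohort data.frame (one or more rows).
#' @param filter A [cohort_filter()].
#' @return Character vector `"short"`/`"long"`, one per row.
#' @export
assign_followup_class <- function(cohort, filter) {
  stopifnot(inherits(filter, "cohort_filter"))
  entry <- pmax(as.numeric(filter$window_start), as.numeric(cohort$diagnosis_date))
  yrs <- (entry - as.numeric(cohort$diagnosis_date)) / YEAR_DAYS
  ifelse(yrs <= filter$followup_class_cut, "short", "long")
}
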