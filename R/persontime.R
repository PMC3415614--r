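## Lexis-style splitting of in-window follow-up into age-group exposure.
##
## Convention: age intervals are half-open [lower, upper) and boundaries are
## crossed at the exact real-valued birthday instant, so a person contributes
## to 65-69 from the instant of the 65th birthday. Calendar period is
## collapsed to the single observation window (no age x period triangles).

#' Abridged age grid
#'
#' @param lower Strictly increasing lower bounds of the age intervals in
#'   years; the last interval is open-ended (`85+` by default).
#' @return Object of class `age_grid` with elements `lower`, `upper`
#'   (`Inf`-terminated), `width` and `labels`.
#' @export
age_grid <- function(lower = seq(50, 85, by = 5)) {
  if (length(lower) < 1L || is.unsorted(lower, strictly = TRUE))
    stop("'lower' must be strictly increasing", call. = FALSE)
  upper <- c(lower[-1L], Inf)
  labels <- ifelse(is.finite(upper),
                   sprintf("%g-%g", lower, upper - 1),
                   sprintf("%g+", lower))
  structure(list(lower = lower, upper = upper, width = upper - lower,
                 labels = labels),
            class = "age_grid")
}

#' @export
print.age_grid <- function(x, ...) {
  cat("Age grid:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Vectorised core: eligible age spans [a1, a2] per person, overlap with each
# grid interval, and death attribution to the interval containing the exit age.
exposure_core <- function(a1, a2, death_age, grid) {
  k <- length(grid$lower)
  n <- length(a1)
  py <- matrix(0, n, k)
  deaths <- integer(k)
  if (n > 0L) {
    lo <- matrix(grid$lower, n, k, byrow = TRUE)
    hi <- matrix(grid$upper, n, k, byrow = TRUE)
    a1m <- matrix(a1, n, k)
    a2m <- matrix(a2, n, k)
    py <- matrix(pmax(0, pmin(a2m, hi) - pmax(a1m, lo)), n, k)
    died <- !is.na(death_age)
    if (any(died)) {
      idx <- findInterval(death_age[died], grid$lower)
      idx <- idx[idx >= 1L & idx <= k]
      deaths <- tabulate(idx, nbins = k)
    }
  }
  list(person_years = py, deaths = deaths)
}

# Eligible observation span of each person in age coordinates, plus the exit
# age of in-window deaths (NA otherwise). Exposure starts at
# max(window_start, diagnosis, attainment of min_age) and ends at
# min(exit, window_end).
eligible_span <- function(cohort, filter) {
  ws <- as.numeric(filter$window_start)
  we <- as.numeric(filter$window_end)
  birth <- as.numeric(cohort$birth_date)
  start_n <- pmax(ws, as.numeric(cohort$diagnosis_date),
                  date_at_age(cohort$birth_date, filter$min_age_in_window))
  end_n <- pmin(as.numeric(cohort$exit_date), we)
  a1 <- (start_n - birth) / YEAR_DAYS
  a2 <- (end_n - birth) / YEAR_DAYS
  death_age <- ifelse(cohort$vital_status == "dead" &
                        as.numeric(cohort$exit_date) <= we &
                        as.numeric(cohort$exit_date) >= start_n,
                      a2, NA_real_)
  list(a1 = a1, a2 = a2, death_age = death_age)
}

#' Split one person's in-window follow-up across age groups
#'
#' @param person A single-row cohort data.frame.
#' @param filter A [cohort_filter()].
#' @param grid An [age_grid()].
#' @return Data.frame with one row per age group touched: `age_group`,
#'   `person_years`, `death` (logical). A person with zero eligible time
#'   yields zero rows.
#' @export
split_person_time <- function(person, filter, grid) {
  stopifnot(inherits(filter, "cohort_filter"), inherits(grid, "age_grid"),
            nrow(person) == 1L)
  sp <- eligible_span(person, filter)
  if (sp$a2 <= sp$a1)
    return(data.frame(age_group = character(), person_years = numeric(),
                      death = logical(), stringsAsFactors = FALSE))
  core <- exposure_core(sp$a1, sp$a2, sp$death_age, grid)
  py <- core$person_years[1L, ]
  touched <- which(py > 0 | core$deaths > 0)
  data.frame(age_group = grid$labels[touched],
             person_years = py[touched],
             death = core$deaths[touched] > 0,
             stringsAsFactors = FALSE)
}

#' Aggregate deaths and person-years over a cohort
#'
#' Sums [split_person_time()] over all persons (vectorised), optionally within
#' strata. Total person-years equal the sum of individual eligible durations
#' to date-arithmetic resolution; total deaths equal the count of in-window
#' deaths among selected persons.
#'
#' @param cohort Selected cohort data.frame (see [select_alive_in_window()]).
#' @param filter A [cohort_filter()].
#' @param grid An [age_grid()].
#' @param stratum Optional vector (length `nrow(cohort)`) of stratum labels;
#'   one exposure table is returned per level, row-bound with a `stratum`
#'   column.
#' @return Data.frame of class `exposure_table`: `age_group`, `deaths`,
#'   `person_years` (plus `stratum` when stratified), rows following the grid.
#' @export
aggregate_exposure <- function(cohort, filter, grid, stratum = NULL) {
  stopifnot(inherits(filter, "cohort_filter"), inherits(grid, "age_grid"))
  one <- function(rows) {
    sp <- eligible_span(cohort[rows, , drop = FALSE], filter)
    ok <- sp$a2 > sp$a1
    core <- exposure_core(sp$a1[ok], sp$a2[ok],
                          sp$death_age[ok], grid)
    data.frame(age_group = grid$labels,
               deaths = core$deaths,
               person_years = if (sum(ok)) colSums(core$person_years) else
                 numeric(length(grid$lower)),
               stringsAsFactors = FALSE)
  }
  if (is.null(stratum)) {
    out <- one(seq_len(nrow(cohort)))
  } else {
    stopifnot(length(stratum) == nrow(cohort))
    pieces <- lapply(split(seq_len(nrow(cohort)), stratum), one)
    out <- do.call(rbind, Map(function(lev, df) cbind(stratum = lev, df),
                              names(pieces), pieces))
    rownames(out) <- NULL
  }
  class(out) <- c("exposure_table", "data.frame")
  attr(out, "grid") <- grid
  out
}
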