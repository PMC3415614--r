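## Multivariate logistic determinants of poor health and walking disability,
## reported as adjusted odds-ratio tables. Fitting is maximum likelihood by
## iteratively reweighted least squares (stats::glm, binomial family) behind
## a surface that adds rank and separation diagnostics; closed 2x2 and
## intercept-only forms serve as oracles in the test suite.

DEFAULT_COVARIATES <- c("sex", "age_group", "ses", "site", "followup",
                        "stage", "comorbidity", "treatment")

# Reference levels mirror the usual reporting convention: male, youngest age
# band, high SES, colon, short follow-up, stage I, no comorbidity, surgery only.
covariate_levels <- function(var, age_breaks) {
  switch(var,
         sex = SEX_LEVELS,
         ses = c("high", "middle", "low", "institutionalized", "unknown"),
         site = SITE_LEVELS,
         followup = c("short", "long"),
         stage = c("I", "II", "III", "IV", "unknown"),
         comorbidity = c("0", "1plus", "unknown"),
         treatment = TREATMENT_LEVELS,
         stop("unknown covariate: ", var, call. = FALSE))
}

#' Build the design for the logistic determinants model
#'
#' Joins the survey to person records, dichotomizes the requested outcome,
#' drops rows with a missing outcome, and assembles the covariate frame with
#' dummy coding against the reporting reference levels (male, youngest age
#' band, high SES, colon, short follow-up, stage I, comorbidity 0, surgery
#' only). `unknown` levels are kept as explicit categories. Covariate levels
#' absent from the data are dropped with a warning.
#'
#' @param survey Survey data.frame.
#' @param cohort Cohort data.frame.
#' @param filter A [cohort_filter()] (for the follow-up class and age floor).
#' @param outcome `"poor_health"` or `"disability"`.
#' @param covariates Subset of
#'   `sex, age_group, ses, site, followup, stage, comorbidity, treatment`,
#'   plus `age_centred` for a continuous age term (centred at 70 years).
#' @param age_coding `"five"` (default): 5-year age bands from the grid floor
#'   with an open 85+ band; `"broad"`: the three display bands 50-64, 65-79,
#'   80+.
#' @return List of class `hle_design`: `data` (model frame with `outcome`
#'   0/1), `formula`, `n_used`, `outcome`.
#' @export
build_design <- function(survey, cohort, filter,
                         outcome = c("poor_health", "disability"),
                         covariates = DEFAULT_COVARIATES,
                         age_coding = c("five", "broad")) {
  outcome <- match.arg(outcome)
  age_coding <- match.arg(age_coding)
  stopifnot(inherits(filter, "cohort_filter"))
  idx <- match(survey$person_id, cohort$person_id)
  if (anyNA(idx))
    stop("survey person_id(s) without a matching person record: ",
         paste(utils::head(unique(survey$person_id[is.na(idx)]), 5L),
               collapse = ", "), call. = FALSE)
  persons <- cohort[idx, , drop = FALSE]
  age <- years_between(persons$birth_date, survey$survey_date)
  state <- if (outcome == "poor_health")
    dichotomize_general_health(survey$general_health_item)
  else dichotomize_walking(survey$walking_item)
  adverse <- if (outcome == "poor_health") "poor" else "limited"
  keep <- state != "missing" & age >= filter$min_age_in_window
  if (!any(keep)) stop("no usable outcome values", call. = FALSE)

  df <- data.frame(outcome = as.integer(state[keep] == adverse))
  age_k <- age[keep]
  persons <- persons[keep, , drop = FALSE]
  for (v in covariates) {
    col <- if (v == "age_group") {
      breaks <- if (age_coding == "five")
        c(seq(filter$min_age_in_window, 85, by = 5), Inf)
      else c(filter$min_age_in_window, 65, 80, Inf)
      lab <- ifelse(is.finite(breaks[-1L]),
                    sprintf("%g-%g", breaks[-length(breaks)], breaks[-1L] - 1),
                    sprintf("%g+", breaks[-length(breaks)]))
      cut(age_k, breaks, labels = lab, right = FALSE)
    } else if (v == "age_centred") {
      age_k - 70
    } else if (v == "followup") {
      factor(assign_followup_class(persons, filter), levels = c("short", "long"))
    } else {
      factor(persons[[v]], levels = covariate_levels(v))
    }
    if (is.factor(col)) {
      present <- levels(col)[levels(col) %in% unique(as.character(col))]
      if (length(present) < nlevels(col))
        warning(sprintf("covariate '%s': dropping absent level(s) %s", v,
                        paste(setdiff(levels(col), present), collapse = ", ")),
                call. = FALSE)
      if (length(present) < 2L) {
        warning(sprintf("covariate '%s' is constant; dropped from the model", v),
                call. = FALSE)
        next
      }
      col <- factor(col, levels = present)
    }
    df[[v]] <- col
  }
  terms <- setdiff(names(df), "outcome")
  if (!length(terms)) stop("no usable covariates", call. = FALSE)
  structure(list(data = df,
                 formula = stats::reformulate(terms, response = "outcome"),
                 n_used = nrow(df), outcome = outcome),
            class = "hle_design")
}

#' Fit the logistic determinants model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`), with an explicit rank check on the design and
#' detection of complete or quasi-complete separation (fitted probabilities
#' within 1e-8 of 0 or 1 together with diverging coefficients raise an error
#' rather than returning silent garbage). Wald standard errors come from the
#' observed information.
#'
#' @param design An `hle_design` from [build_design()], or a numeric model
#'   matrix (including the intercept column) when `y` is supplied.
#' @param y Optional 0/1 response vector for the matrix interface.
#' @return Data.frame of class `logistic_fit`: `term, beta, se, OR, ci_low,
#'   ci_high, p, significant`, with attributes `n_used`, `converged`,
#'   `iterations`.
#' @export
fit_logistic <- function(design, y = NULL) {
  if (inherits(design, "hle_design")) {
    X <- stats::model.matrix(design$formula, design$data)
    y <- design$data$outcome
  } else {
    X <- as.matrix(design)
    if (is.null(y)) stop("'y' is required with a matrix design", call. = FALSE)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; drop aliased terms", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 50L)))
  mu <- fit$fitted.values
  if (any((mu < 1e-8 | mu > 1 - 1e-8) & abs(X %*% fit$coefficients) > 10))
    stop("complete or quasi-complete separation detected: some fitted ",
         "probabilities are numerically 0 or 1 with diverging coefficients",
         call. = FALSE)
  beta <- fit$coefficients
  W <- mu * (1 - mu)
  info <- crossprod(X, X * W)       # observed = expected information here
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(term = names(beta), beta = unname(beta), se = unname(se),
                    OR = exp(unname(beta)),
                    ci_low = exp(unname(beta - 1.96 * se)),
                    ci_high = exp(unname(beta + 1.96 * se)),
                    p = unname(p), significant = unname(p < 0.05),
                    stringsAsFactors = FALSE)
  class(out) <- c("logistic_fit", "data.frame")
  attr(out, "n_used") <- length(y)
  attr(out, "converged") <- fit$converged
  attr(out, "iterations") <- fit$iter
  out
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fit: n = %d, converged in %d IRLS iterations\n",
              attr(x, "n_used"), attr(x, "iterations")))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Crude odds ratio from a 2x2 table
#'
#' `(a d)/(b c)` with the Woolf (log-scale) 95\% confidence interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Serves as the
#' closed-form oracle for single-covariate logistic fits.
#'
#' @param a,b,c,d Cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases. All must be positive.
#' @param correction Continuity correction added to every cell when a cell is
#'   zero (`NULL`, the default, refuses zero cells instead).
#' @return List with `OR`, `ci_low`, `ci_high`, `log_se`.
#' @export
crude_odds_ratio <- function(a, b, c, d, correction = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  if (any(cells == 0)) {
    if (is.null(correction))
      stop("zero cell in the 2x2 table; supply a continuity correction ",
           "(e.g. correction = 0.5)", call. = FALSE)
    cells <- cells + correction
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  log_se <- sqrt(sum(1 / cells))
  list(OR = unname(or),
       ci_low = unname(exp(log(or) - 1.96 * log_se)),
       ci_high = unname(exp(log(or) + 1.96 * log_se)),
       log_se = unname(log_se))
}

#' Adjusted odds-ratio table for one outcome
#'
#' Convenience wrapper: builds the design, fits the model, and lays the
#' result out as a reporting table with one row per non-reference covariate
#' level (reference levels carry OR = 1 by construction and are omitted).
#'
#' @inheritParams build_design
#' @return A `logistic_fit` data.frame.
#' @export
determinants_table <- function(survey, cohort, filter,
                               outcome = c("poor_health", "disability"),
                               covariates = DEFAULT_COVARIATES,
                               age_coding = c("five", "broad")) {
  design <- build_design(survey, cohort, filter, outcome,
                         covariates = covariates, age_coding = age_coding)
  fit_logistic(design)
}
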