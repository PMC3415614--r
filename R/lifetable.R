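## Abridged period life table from age-grouped deaths and person-years.
##
## Standard actuarial identities on an abridged grid:
##   m_x = D_x / P_x                      central death rate
##   q_x = n_x m_x / (1 + (n_x - a_x) m_x)  capped at 1; open interval q = 1
##   d_x = l_x q_x;  l_{x+n} = l_x - d_x
##   L_x = n_x l_{x+n} + a_x d_x;  open interval L = l / m
##   T_x = sum_{y >= x} L_y;  e_x = T_x / l_x
## with a_x = n_x/2 (midpoint) by default for closed intervals.

#' Central death rates from an exposure table
#'
#' @param exposure An unstratified `exposure_table` (or data.frame with
#'   `deaths` and `person_years`).
#' @param zero_cell Rule for cells with zero person-years and zero deaths:
#'   `"zero"` (default) sets `m = 0`; `"error"` refuses. Zero person-years
#'   with positive deaths is always an error.
#' @return Numeric vector of death rates per person-year, one per age group.
#' @export
death_rates <- function(exposure, zero_cell = c("zero", "error")) {
  zero_cell <- match.arg(zero_cell)
  if (!is.null(exposure$stratum))
    stop("'exposure' must be unstratified; split by stratum first", call. = FALSE)
  D <- exposure$deaths
  P <- exposure$person_years
  if (any(P == 0 & D > 0))
    stop("deaths recorded in age group(s) with zero person-years: ",
         paste(exposure$age_group[P == 0 & D > 0], collapse = ", "), call. = FALSE)
  if (any(P == 0) && zero_cell == "error")
    stop("zero person-years in age group(s): ",
         paste(exposure$age_group[P == 0], collapse = ", "), call. = FALSE)
  m <- ifelse(P > 0, D / P, 0)
  if (any(P > 0 & D == 0))
    message("death_rates: ", sum(P > 0 & D == 0),
            " age group(s) with exposure but no deaths (m = 0)")
  m
}

#' Build an abridged period life table
#'
#' @param m Vector of central death rates, one per interval of `grid`.
#' @param grid An [age_grid()]; the last interval is open-ended and closed by
#'   `L = l/m`, which requires a positive rate there.
#' @param a_convention Average years lived in the interval by those dying in
#'   it: `"half"` (default, `a_x = n_x/2`) or a numeric vector of `a_x` values
#'   for the closed intervals.
#' @param radix Survivors at the first exact age (100,000 by default).
#' @return Data.frame of class `life_table` with columns
#'   `age, n, m, a, q, l, d, L, T, e`.
#' @export
build_life_table <- function(m, grid, a_convention = "half", radix = 1e5) {
  stopifnot(inherits(grid, "age_grid"))
  k <- length(grid$lower)
  if (length(m) != k) stop("'m' must have one rate per age interval", call. = FALSE)
  if (any(m < 0) || any(!is.finite(m))) stop("'m' must be finite and >= 0", call. = FALSE)
  if (m[k] <= 0)
    stop("open-interval death rate is zero; the table cannot be closed ",
         "(supply a positive rate for the last age group)", call. = FALSE)
  n <- grid$width
  a <- if (identical(a_convention, "half")) n / 2 else {
    stopifnot(is.numeric(a_convention), length(a_convention) %in% c(1L, k))
    rep_len(a_convention, k)
  }
  q <- pmin(1, n * m / (1 + (n - a) * m))
  q[k] <- 1
  l <- numeric(k)
  l[1] <- radix
  for (i in seq_len(k - 1L)) l[i + 1L] <- l[i] * (1 - q[i])
  d <- l * q
  L <- n * c(l[-1L], 0) + a * d
  L[k] <- l[k] / m[k]
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)
  out <- data.frame(age = grid$lower, n = n, m = m, a = a, q = q,
                    l = l, d = d, L = L, T = Tx, e = e)
  class(out) <- c("life_table", "data.frame")
  attr(out, "grid") <- grid
  out
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat(sprintf("Abridged life table (%d age groups, radix %g)\n",
              nrow(x), x$l[1]))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Remaining life expectancy at a grid boundary
#'
#' @param lt A [build_life_table()] result.
#' @param age Exact age in years; must be one of the grid lower bounds (no
#'   interpolation is performed).
#' @return `e_x` in years.
#' @export
life_expectancy <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(age, lt$age)
  if (is.na(i)) {
    below <- max(lt$age[lt$age <= age], -Inf)
    above <- min(lt$age[lt$age >= age], Inf)
    stop(sprintf("age %g is not a grid boundary (nearest: %g and %g)",
                 age, below, above), call. = FALSE)
  }
  lt$e[i]
}
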