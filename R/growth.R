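# Geometric growth: the constant annual rate r (percent/year) linking two
# census counts through P_t = P_0 (1 + r/100)^t. Rates are exchanged in
# percent per year throughout the package; conversion to a multiplicative
# factor happens once, here.

rate_value <- function(rate) {
  if (inherits(rate, "growth_rate")) rate$rate else as.numeric(rate)
}

#' Construct a growth-rate record
#'
#' @param rate annual geometric growth rate in percent per year (may be
#'   negative, must exceed -100)
#' @param period_start,period_end optional census years delimiting the period
#'   the rate was observed over
#' @param stratum population stratum the rate refers to, e.g. `"total"` or
#'   `"age_65_plus"`
#' @return an object of class `growth_rate`
#' @export
growth_rate <- function(rate, period_start = NA_integer_,
                        period_end = NA_integer_, stratum = "total") {
  rate <- as.numeric(rate)
  if (!is.finite(rate) || rate <= -100) {
    stop_savr("savr_domain_error", "growth rate must be finite and > -100")
  }
  if (!is.na(period_start) && !is.na(period_end) && period_end <= period_start) {
    stop_savr("savr_domain_error", "period_end must exceed period_start")
  }
  structure(
    list(rate = rate, period_start = as.integer(period_start),
         period_end = as.integer(period_end), stratum = stratum),
    class = "growth_rate"
  )
}

#' @export
print.growth_rate <- function(x, ...) {
  period <- if (is.na(x$period_start)) "" else {
    sprintf(" over %d-%d", x$period_start, x$period_end)
  }
  cat(sprintf("<growth_rate> %.2f %%/yr (%s%s)\n", x$rate, x$stratum, period))
  invisible(x)
}

#' @export
as.double.growth_rate <- function(x, ...) x$rate

#' Geometric growth rate between two population counts
#'
#' Solves \eqn{P_{end} = P_{start} (1 + r/100)^{t}} for the annual rate
#' \eqn{r = 100 ((P_{end}/P_{start})^{1/t} - 1)}; the exact inverse of
#' [project_population()]. Report rates rounded to 2 decimals.
#'
#' @param p_start,p_end population counts at the period boundaries (positive)
#' @param years period length in years, or `NULL` to use
#'   `period_end - period_start`
#' @param period_start,period_end optional census years, recorded in the
#'   result
#' @param stratum population stratum label
#' @return a [growth_rate()] in percent per year
#' @examples
#' geometric_growth_rate(535894 / 1.014^10, 535894, 10)
#' @export
geometric_growth_rate <- function(p_start, p_end, years = NULL,
                                  period_start = NA_integer_,
                                  period_end = NA_integer_,
                                  stratum = "total") {
  if (is.null(years)) {
    if (is.na(period_start) || is.na(period_end)) {
      stop_savr("savr_domain_error",
                "supply either years or both period_start and period_end")
    }
    years <- period_end - period_start
  }
  if (p_start <= 0 || p_end <= 0) {
    stop_savr("savr_domain_error", "populations must be positive")
  }
  if (years <= 0) stop_savr("savr_domain_error", "years must be positive")
  growth_rate(100 * ((p_end / p_start)^(1 / years) - 1),
              period_start, period_end, stratum)
}

#' Project a population at a constant geometric rate
#'
#' \eqn{P_t = P_0 (1 + r/100)^t}. Full precision is carried by default so that
#' chained projections never compound rounding error; set `round = TRUE` for
#' report-scale integer persons.
#'
#' @param p0 starting population (non-negative)
#' @param rate annual rate in percent per year (numeric or [growth_rate()])
#' @param years projection horizon in years (non-negative)
#' @param round round to integer persons?
#' @return projected population
#' @examples
#' project_population(535894, 1.40, 10, round = TRUE)
#' @export
project_population <- function(p0, rate, years, round = FALSE) {
  r <- rate_value(rate)
  if (any(p0 < 0)) stop_savr("savr_domain_error", "p0 must be non-negative")
  if (any(years < 0)) stop_savr("savr_domain_error", "years must be non-negative")
  if (any(r <= -100)) stop_savr("savr_domain_error", "rate must exceed -100")
  out <- p0 * (1 + r / 100)^years
  if (round) report_persons(out) else out
}

#' Population doubling time
#'
#' Years needed for a population to double at a constant geometric rate:
#' \eqn{t_2 = \ln 2 / \ln(1 + r/100)}. Only defined for positive rates — a
#' stagnant or shrinking population never doubles.
#'
#' @param rate annual rate in percent per year (numeric or [growth_rate()])
#' @return doubling time in years
#' @examples
#' doubling_time(1.40) # about 50 years
#' @export
doubling_time <- function(rate) {
  r <- rate_value(rate)
  if (any(r <= 0)) {
    stop_savr("savr_no_doubling_error",
              "doubling time is undefined for rates <= 0")
  }
  log(2) / log1p(r / 100)
}
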