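# Demand translation: decade surgery counts -> decade "prevalence" (the
# decade-cumulative SAVR-per-elderly ratio, not a point prevalence of
# disease) -> expected surgical volumes for projected elderly populations.

#' Construct a surgery-decade record
#'
#' One decade of surgical aortic valve replacements (SAVR) performed in
#' patients aged 65 and over.
#'
#' @param start_year,end_year decade boundaries; must be exactly 10 years
#'   apart
#' @param n_surgeries SAVR count over the decade (non-negative integer)
#' @return a one-row tibble of class `surgery_decade`
#' @examples
#' surgery_decade(2011, 2021, 2424)
#' @export
surgery_decade <- function(start_year, end_year, n_surgeries) {
  reg <- surgery_registry(start_year, end_year, n_surgeries)
  if (nrow(reg) != 1) {
    stop_savr("savr_domain_error", "surgery_decade takes a single decade")
  }
  class(reg) <- c("surgery_decade", class(reg))
  reg
}

#' Construct a surgery registry (one or more decades)
#'
#' @param start_year,end_year integer vectors of decade boundaries
#' @param n_surgeries SAVR counts, one per decade
#' @return a tibble of class `surgery_registry`
#' @export
surgery_registry <- function(start_year, end_year, n_surgeries) {
  df <- tibble::tibble(
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    n_surgeries = as.numeric(n_surgeries)
  )
  if (any(df$end_year - df$start_year != 10)) {
    stop_savr("savr_validation_error",
              "each registry decade must span exactly 10 years")
  }
  if (any(is.na(df$n_surgeries) | df$n_surgeries < 0 |
            df$n_surgeries != floor(df$n_surgeries))) {
    stop_savr("savr_validation_error",
              "n_surgeries must be non-negative integers")
  }
  structure(df, class = c("surgery_registry", class(tibble::tibble())))
}

#' Decade prevalence of surgical intervention
#'
#' The decade-cumulative ratio of SAVR performed in patients 65+ to the
#' end-of-decade census population aged 65+:
#' \deqn{\pi = 100 \times S / P_{65+}^{end}.}
#' Despite the name this is a surgery-to-population ratio over a decade, not a
#' point prevalence of aortic stenosis. Report to 2 decimals; full precision
#' is returned.
#'
#' @param decade a [surgery_decade()] or a bare surgery count
#' @param pop_65_plus_at_end census 65+ population at the decade's end year
#'   (positive)
#' @return prevalence in percent, full precision
#' @examples
#' decade_prevalence(2424, 535894) # ~0.45
#' @export
decade_prevalence <- function(decade, pop_65_plus_at_end) {
  n <- if (inherits(decade, "surgery_registry") || is.data.frame(decade)) {
    decade$n_surgeries
  } else {
    as.numeric(decade)
  }
  if (any(pop_65_plus_at_end <= 0)) {
    stop_savr("savr_domain_error", "population must be positive")
  }
  if (any(n < 0)) stop_savr("savr_domain_error", "surgeries must be >= 0")
  100 * n / pop_65_plus_at_end
}

#' Expected surgeries for a projected elderly population
#'
#' Applies a decade prevalence to a projected 65+ population:
#' `round(prevalence/100 * population)` (half-up).
#'
#' @param prevalence decade prevalence in percent (non-negative)
#' @param projected_pop_65_plus projected 65+ population
#' @return expected SAVR count per decade, integer
#' @examples
#' projected_surgeries(0.45, 650506) # 2927
#' @export
projected_surgeries <- function(prevalence, projected_pop_65_plus) {
  if (any(prevalence < 0)) {
    stop_savr("savr_domain_error", "prevalence must be >= 0")
  }
  if (any(projected_pop_65_plus < 0)) {
    stop_savr("savr_domain_error", "population must be >= 0")
  }
  report_persons(prevalence / 100 * projected_pop_65_plus)
}

#' Summarise projected demand against a reference decade
#'
#' Computes the per-decade increase of projected surgeries over an observed
#' reference decade and its per-year equivalent. The exact one-decimal
#' per-year value is always surfaced; the reported integer follows the chosen
#' rounding policy (`"exact"` keeps one decimal, `"ceil"` rounds up — the
#' conservative "at least this many more per year" reading — and `"nearest"`
#' rounds half-up).
#'
#' @param projected expected surgeries in the projected decade
#' @param reference a [surgery_decade()], the observed comparison decade
#' @param rounding_policy `"exact"`, `"ceil"` or `"nearest"`
#' @return a list of class `demand_estimate`: `projected`, `reference`,
#'   `decade_increase`, `per_year_exact`, `per_year_ceil`,
#'   `per_year_nearest`, `per_year_reported`, `policy`
#' @examples
#' demand_summary(2927, surgery_decade(2011, 2021, 2424))
#' @export
demand_summary <- function(projected, reference,
                           rounding_policy = c("exact", "ceil", "nearest")) {
  rounding_policy <- match.arg(rounding_policy)
  if (projected < 0) stop_savr("savr_domain_error", "projected must be >= 0")
  stopifnot(inherits(reference, "surgery_decade"))
  inc <- projected - reference$n_surgeries
  per_year <- inc / 10
  structure(
    list(
      projected = projected, reference = reference,
      decade_increase = inc,
      per_year_exact = round(per_year, 1),
      per_year_ceil = ceiling(per_year),
      per_year_nearest = report_persons(per_year),
      per_year_reported = switch(rounding_policy,
        exact = round(per_year, 1),
        ceil = ceiling(per_year),
        nearest = report_persons(per_year)
      ),
      policy = rounding_policy
    ),
    class = "demand_estimate"
  )
}

#' @export
print.demand_estimate <- function(x, ...) {
  cat(sprintf(
    "<demand_estimate> %d projected vs %d observed: +%g per decade (+%s/yr, policy %s)\n",
    x$projected, x$reference$n_surgeries, x$decade_increase,
    format(x$per_year_reported), x$policy
  ))
  invisible(x)
}

#' Demand table across scenarios
#'
#' One row per scenario: projected 65+ population, expected surgeries at the
#' given prevalence, and the increments over the reference decade.
#'
#' @param projected_pops named numeric vector of projected 65+ populations,
#'   one element per scenario
#' @param prevalence decade prevalence in percent
#' @param reference a [surgery_decade()]
#' @param rounding_policy passed to [demand_summary()]
#' @return tibble with columns `scenario`, `projected_pop_65_plus`,
#'   `projected_surgeries`, `decade_increase`, `per_year_exact`,
#'   `per_year_reported`
#' @examples
#' demand_table(c(decreasing = 650506, stagnation = 688335), 0.45,
#'              surgery_decade(2011, 2021, 2424))
#' @export
demand_table <- function(projected_pops, prevalence, reference,
                         rounding_policy = "exact") {
  rows <- lapply(names(projected_pops), function(scen) {
    s <- projected_surgeries(prevalence, projected_pops[[scen]])
    d <- demand_summary(s, reference, rounding_policy)
    tibble::tibble(
      scenario = scen,
      projected_pop_65_plus = report_persons(projected_pops[[scen]]),
      projected_surgeries = s,
      decade_increase = d$decade_increase,
      per_year_exact = d$per_year_exact,
      per_year_reported = d$per_year_reported
    )
  })
  do.call(rbind, rows)
}

#' Linear trend in annual surgery counts
#'
#' Ordinary least-squares fit of surgeries per year on calendar year — a
#' generic utility for registries that do publish annual series.
#'
#' @param years calendar years (at least 3 distinct values)
#' @param surgeries surgeries performed in each year
#' @return list with `slope` (surgeries/year per year), `intercept`,
#'   `r_squared` and `p_value` (two-sided, slope = 0)
#' @examples
#' annual_trend(2001:2010, 100 + 8 * (0:9) + rnorm(10))
#' @export
annual_trend <- function(years, surgeries) {
  if (length(years) < 3 || length(surgeries) != length(years)) {
    stop_savr("savr_insufficient_data_error",
              "need >= 3 (year, surgeries) points")
  }
  if (stats::var(years) == 0) {
    stop_savr("savr_fit_error", "years have zero variance")
  }
  if (stats::var(surgeries) == 0) {
    # a flat series has no trend and an undefined coefficient of determination
    return(list(slope = 0, intercept = surgeries[1], r_squared = NA_real_,
                p_value = NA_real_))
  }
  fit <- stats::lm(surgeries ~ years)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    # a perfectly linear series is a legitimate input, not a numerical problem
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4])
  )
}
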