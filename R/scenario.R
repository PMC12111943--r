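# Two-phase, two-scenario projection engine. A scenario is a base annual
# growth rate (the last observed inter-census rate) plus a per-decade
# decrement Delta, an *absolute* percentage-point subtraction that may push
# rates negative. The two presets differ only in when the decrement starts:
#
#   decreasing  — the slowdown observed between past decades continues, so
#                 phase 1 (first projected decade) already runs at
#                 base - Delta, phase 2 at base - 2 Delta, ...
#   stagnation  — the base rate is held for phase 1 and the decrement applies
#                 only from phase 2 on (base, base - Delta, ...).
#
# A strictly constant-rate variant is the stagnation preset with Delta = 0.

#' Construct a projection scenario
#'
#' @param name scenario label; `"decreasing"` and `"stagnation"` are the two
#'   presets (which fix `decrement_from_first_phase`), any other string gives
#'   a custom scenario
#' @param base_rate observed annual growth rate, percent/year
#' @param decrement per-decade absolute reduction of the rate, percentage
#'   points (may be 0)
#' @param phase_length years per projection phase (default one decade)
#' @param n_phases number of chained phases (default 2, i.e. a 20-year
#'   horizon)
#' @param decrement_from_first_phase apply the decrement already in phase 1?
#'   Required for custom scenarios; forced to `TRUE`/`FALSE` by the
#'   `"decreasing"`/`"stagnation"` presets.
#' @return an object of class `scenario_spec`
#' @examples
#' scenario_spec("stagnation", base_rate = 1.40, decrement = 0.29)
#' @export
scenario_spec <- function(name, base_rate, decrement = 0, phase_length = 10,
                          n_phases = 2, decrement_from_first_phase = NULL) {
  if (phase_length <= 0) {
    stop_savr("savr_domain_error", "phase_length must be positive")
  }
  if (n_phases < 1) stop_savr("savr_domain_error", "n_phases must be >= 1")
  if (identical(name, "decreasing")) {
    decrement_from_first_phase <- TRUE
  } else if (identical(name, "stagnation")) {
    decrement_from_first_phase <- FALSE
  } else if (is.null(decrement_from_first_phase)) {
    stop_savr("savr_domain_error",
              "custom scenarios must set decrement_from_first_phase")
  }
  structure(
    list(name = name, base_rate = as.numeric(base_rate),
         decrement = as.numeric(decrement),
         phase_length = as.numeric(phase_length),
         n_phases = as.integer(n_phases),
         decrement_from_first_phase = isTRUE(decrement_from_first_phase)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec '%s'> base %.2f %%/yr, decrement %.2f pp/decade (from phase %d), %d x %g yr\n",
    x$name, x$base_rate, x$decrement,
    if (x$decrement_from_first_phase) 1L else 2L, x$n_phases, x$phase_length
  ))
  invisible(x)
}

#' Per-phase growth rates of a scenario
#'
#' Phase \eqn{i} (1-based) runs at `base_rate - decrement * (i - 1 + offset)`
#' where the offset is 1 when the decrement applies from the first phase and
#' 0 otherwise. Rates may legitimately go negative.
#'
#' @param spec a [scenario_spec()]
#' @return numeric vector of annual rates, one per phase
#' @examples
#' phase_rates(scenario_spec("decreasing", 1.40, 0.29)) # 1.11, 0.82
#' @export
phase_rates <- function(spec) {
  offset <- if (spec$decrement_from_first_phase) 1 else 0
  spec$base_rate - spec$decrement * (seq_len(spec$n_phases) - 1 + offset)
}

#' Run a projection scenario
#'
#' Chains [project_population()] over the scenario's phases at full precision;
#' the per-phase end populations are additionally reported rounded to integer
#' persons.
#'
#' @param p0 population at the base year (positive)
#' @param base_year calendar year `p0` refers to
#' @param spec a [scenario_spec()]
#' @param stratum label for the projected stratum
#' @return an object of class `projection_result` with elements `scenario`,
#'   `stratum`, `p0`, `base_year`, `phase_rates`, `phase_end_years`,
#'   `phase_end_populations` (full precision) and `reported` (integer persons)
#' @examples
#' run_scenario(535894, 2021, scenario_spec("stagnation", 1.40, 0.29))
#' @export
run_scenario <- function(p0, base_year, spec, stratum = "total") {
  if (p0 <= 0) stop_savr("savr_domain_error", "p0 must be positive")
  rates <- phase_rates(spec)
  pops <- numeric(spec$n_phases)
  p <- p0
  for (i in seq_along(rates)) {
    p <- project_population(p, rates[i], spec$phase_length)
    pops[i] <- p
  }
  structure(
    list(
      scenario = spec, stratum = stratum, p0 = p0,
      base_year = as.integer(base_year),
      phase_rates = rates,
      phase_end_years = as.integer(base_year + spec$phase_length *
                                     seq_len(spec$n_phases)),
      phase_end_populations = pops,
      reported = report_persons(pops)
    ),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result '%s', %s> %s (%d) ->\n",
              x$scenario$name, x$stratum,
              format(x$p0, big.mark = ","), x$base_year))
  for (i in seq_along(x$phase_rates)) {
    cat(sprintf("  %d: %s at %.2f %%/yr\n", x$phase_end_years[i],
                format(x$reported[i], big.mark = ","), x$phase_rates[i]))
  }
  invisible(x)
}

#' Two-scenario, two-stratum projection table
#'
#' Projects the total and the 65+ populations under the decreasing-rate and
#' stagnation presets, producing the familiar scenario-by-stratum-by-decade
#' layout (base census row plus one projected value per phase end-year).
#'
#' @param p0_total,p0_65plus base-year populations of the two strata
#' @param base_rates named numeric `c(total = ..., age_65_plus = ...)`, the
#'   observed annual rates of the last inter-census decade, percent/year
#' @param decrements named numeric as `base_rates`, the per-decade rate
#'   reductions in percentage points
#' @param base_year census year of the base populations
#' @param phase_length,n_phases passed to [scenario_spec()]
#' @return tibble with columns `scenario` (`census`, `decreasing`,
#'   `stagnation`), `stratum`, `year`, `population` (integer persons),
#'   `rate` (the annual rate that produced the value, `NA` for the census row)
#' @examples
#' scenario_table(2319319, 535894,
#'                base_rates = c(total = 0.19, age_65_plus = 1.40),
#'                decrements = c(total = 0.30, age_65_plus = 0.29))
#' @export
scenario_table <- function(p0_total, p0_65plus, base_rates, decrements,
                           base_year = 2021, phase_length = 10, n_phases = 2) {
  strata <- c("total", "age_65_plus")
  if (!all(strata %in% names(base_rates)) || !all(strata %in% names(decrements))) {
    stop_savr("savr_domain_error",
              "base_rates and decrements need elements 'total' and 'age_65_plus'")
  }
  p0 <- c(total = p0_total, age_65_plus = p0_65plus)
  rows <- list(tibble::tibble(
    scenario = "census", stratum = strata, year = as.integer(base_year),
    population = report_persons(unname(p0[strata])), rate = NA_real_
  ))
  for (scen in c("decreasing", "stagnation")) {
    for (st in strata) {
      spec <- scenario_spec(scen, base_rates[[st]], decrements[[st]],
                            phase_length = phase_length, n_phases = n_phases)
      res <- run_scenario(p0[[st]], base_year, spec, stratum = st)
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = scen, stratum = st, year = res$phase_end_years,
        population = res$reported, rate = res$phase_rates
      )
    }
  }
  do.call(rbind, rows)
}
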