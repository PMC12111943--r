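# End-to-end orchestration: load (or synthesise) inputs, compute indices and
# their across-year comparison, estimate inter-census growth rates, project
# the two scenarios, and translate the projected elderly population into
# expected SAVR volumes. All report rounding (integer persons, 1-decimal
# indices, 2-decimal rates and prevalences) goes through the helpers in
# utils.R; the applied prevalence is the 2-decimal reported value, as a
# registry analyst would carry it forward.

REPORT_SCHEMA_VERSION <- "1.0"

#' Configuration for a full pipeline run
#'
#' Exactly one input source must be given: CSV paths (census panel plus
#' surgery registry) or a [synthetic_config()].
#'
#' @param census_csv,registry_csv input file paths (see [read_census_csv()]
#'   and [read_registry_csv()] for the schemas)
#' @param synthetic a [synthetic_config()] generating both inputs instead
#' @param horizon last projected year; must exceed the last census year by a
#'   whole number of phases
#' @param phase_length years per projection phase
#' @param prevalence_policy which observed decade's prevalence to carry
#'   forward (only `"latest"` is implemented)
#' @param rounding_policy per-year increment reporting, see [demand_summary()]
#' @param out_dir directory for report files, or `NULL` to skip writing
#' @param verbose log derived rates and rounding to stderr?
#' @return a list of class `run_config`
#' @export
run_config <- function(census_csv = NULL, registry_csv = NULL,
                       synthetic = NULL, horizon = 2041, phase_length = 10,
                       prevalence_policy = "latest",
                       rounding_policy = "exact",
                       out_dir = NULL, verbose = FALSE) {
  from_files <- !is.null(census_csv)
  if (from_files == !is.null(synthetic)) {
    stop_savr("savr_config_error",
              "supply exactly one input source: census_csv or synthetic")
  }
  if (from_files && is.null(registry_csv)) {
    stop_savr("savr_config_error", "census_csv requires registry_csv")
  }
  if (!identical(prevalence_policy, "latest")) {
    stop_savr("savr_config_error", "only prevalence_policy = 'latest' is implemented")
  }
  structure(
    list(census_csv = census_csv, registry_csv = registry_csv,
         synthetic = synthetic, horizon = as.integer(horizon),
         phase_length = as.numeric(phase_length),
         prevalence_policy = prevalence_policy,
         rounding_policy = rounding_policy,
         out_dir = out_dir, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full demand-projection analysis
#'
#' Pipeline: validate inputs -> aging/longevity index tables with
#' Kruskal-Wallis/Dunn across-year comparison -> regional inter-census
#' geometric growth rates for the total and 65+ strata -> two-phase
#' decreasing/stagnation scenario projections to the horizon -> decade
#' prevalence from the latest registry decade -> expected SAVR per scenario.
#' The observed per-decade rate decline supplies the scenario decrement; with
#' only two census waves the decrement is zero (both scenarios then coincide
#' with constant-rate projection).
#'
#' @param config a [run_config()]
#' @return invisibly, a list report bundle: `inputs`, `indices` (tables,
#'   summaries, comparisons), `growth` (per-decade regional rates),
#'   `doubling_time_65`, `scenarios` (tibble from [scenario_table()]),
#'   `demand` (tibble from [demand_table()]), `prevalence`, `files`
#' @examples
#' cfg <- run_config(synthetic = synthetic_config(seed = 9))
#' res <- run_analysis(cfg)
#' res$demand
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  verbose <- config$verbose

  if (!is.null(config$synthetic)) {
    panel <- generate_panel(config$synthetic)
    registry <- generate_registry(panel, config$synthetic$true_prevalence,
                                  seed = config$synthetic$seed)
    log_msg(verbose, "generated synthetic panel: %d municipalities x %d years",
            length(panel_municipalities(panel)), length(panel_years(panel)))
  } else {
    panel <- read_census_csv(config$census_csv)
    registry <- read_registry_csv(config$registry_csv)
    log_msg(verbose, "read %s: %d records", config$census_csv, nrow(panel))
  }

  years <- panel_years(panel)
  base_year <- years[length(years)]
  if (config$horizon <= base_year) {
    stop_savr("savr_config_error", "horizon must exceed the last census year")
  }
  span <- config$horizon - base_year
  if (span %% config$phase_length != 0) {
    stop_savr("savr_config_error",
              "horizon - last census year must be a multiple of phase_length")
  }
  n_phases <- as.integer(span / config$phase_length)

  # --- indices -------------------------------------------------------------
  have_75 <- !anyNA(panel$pop_75_plus[panel$sex == "all"])
  indices <- list()
  for (idx in c("aging", if (have_75) "longevity")) {
    tab <- index_table(panel, idx)
    cmp <- if (length(years) >= 2) compare_years(tab) else NULL
    indices[[idx]] <- list(table = tab, summary = index_summary(tab),
                           comparison = cmp)
    if (!is.null(cmp)) {
      log_msg(verbose, "%s index: Kruskal-Wallis H = %.3f, p = %.3g",
              idx, cmp$omnibus_statistic, cmp$omnibus_p)
    }
  }

  # --- regional growth rates ----------------------------------------------
  region <- lapply(years, function(y) aggregate_region(panel, "all", y))
  names(region) <- years
  rates <- list(total = numeric(0), age_65_plus = numeric(0))
  for (i in seq_len(length(years) - 1)) {
    a <- region[[i]]; b <- region[[i + 1]]
    span_i <- years[i + 1] - years[i]
    rates$total <- c(rates$total,
                     geometric_growth_rate(a$pop_total, b$pop_total, span_i)$rate)
    rates$age_65_plus <- c(
      rates$age_65_plus,
      geometric_growth_rate(a$pop_65_plus, b$pop_65_plus, span_i)$rate
    )
    log_msg(verbose, "%d-%d: total %.2f %%/yr, 65+ %.2f %%/yr",
            years[i], years[i + 1],
            report_rate(rates$total[i]), report_rate(rates$age_65_plus[i]))
  }
  n_dec <- length(rates$total)
  base_rates <- c(total = rates$total[n_dec],
                  age_65_plus = rates$age_65_plus[n_dec])
  decrements <- if (n_dec >= 2) {
    c(total = rates$total[n_dec - 1] - rates$total[n_dec],
      age_65_plus = rates$age_65_plus[n_dec - 1] - rates$age_65_plus[n_dec])
  } else {
    c(total = 0, age_65_plus = 0)
  }
  log_msg(verbose, "decrements: total %.2f pp, 65+ %.2f pp",
          decrements[["total"]], decrements[["age_65_plus"]])

  # --- scenarios -----------------------------------------------------------
  p0 <- region[[length(region)]]
  scen_tab <- scenario_table(
    p0_total = p0$pop_total, p0_65plus = p0$pop_65_plus,
    base_rates = base_rates, decrements = decrements,
    base_year = base_year, phase_length = config$phase_length,
    n_phases = n_phases
  )

  dt65 <- if (base_rates[["age_65_plus"]] > 0) {
    doubling_time(base_rates[["age_65_plus"]])
  } else {
    NA_real_
  }

  # --- demand --------------------------------------------------------------
  last_dec <- registry[which.max(registry$end_year), , drop = FALSE]
  end_pop <- aggregate_region(panel, "all", last_dec$end_year)$pop_65_plus
  prev_exact <- decade_prevalence(last_dec$n_surgeries, end_pop)
  prev_applied <- report_rate(prev_exact)
  log_msg(verbose,
          "decade prevalence %d-%d: %.4f%% (applied at reported %.2f%%)",
          last_dec$start_year, last_dec$end_year, prev_exact, prev_applied)

  final <- scen_tab[scen_tab$stratum == "age_65_plus" &
                      scen_tab$year == config$horizon &
                      scen_tab$scenario != "census", , drop = FALSE]
  proj_pops <- stats::setNames(final$population, final$scenario)
  reference <- surgery_decade(last_dec$start_year, last_dec$end_year,
                              last_dec$n_surgeries)
  dem_tab <- demand_table(proj_pops, prev_applied, reference,
                          rounding_policy = config$rounding_policy)

  bundle <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    inputs = list(panel = panel, registry = registry, base_year = base_year,
                  horizon = config$horizon),
    indices = indices,
    growth = list(years = years, rates = rates, base_rates = base_rates,
                  decrements = decrements),
    doubling_time_65 = dt65,
    scenarios = scen_tab,
    prevalence = list(exact = prev_exact, applied = prev_applied,
                      decade = c(last_dec$start_year, last_dec$end_year)),
    demand = dem_tab,
    files = NULL
  )
  if (!is.null(config$out_dir)) {
    bundle$files <- write_report_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

# Serialise the report bundle: tidy CSVs plus a versioned JSON summary.
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (idx in names(bundle$indices)) {
    vpath <- file.path(out_dir, sprintf("index_%s.csv", idx))
    spath <- file.path(out_dir, sprintf("index_%s_summary.csv", idx))
    write_index_csv(bundle$indices[[idx]]$table, vpath, spath)
    files[[sprintf("index_%s", idx)]] <- vpath
    files[[sprintf("index_%s_summary", idx)]] <- spath
  }
  scen_path <- file.path(out_dir, "scenario_table.csv")
  utils::write.csv(as.data.frame(bundle$scenarios), scen_path,
                   row.names = FALSE, quote = TRUE)
  files$scenario_table <- scen_path
  dem_path <- file.path(out_dir, "demand_table.csv")
  utils::write.csv(as.data.frame(bundle$demand), dem_path,
                   row.names = FALSE, quote = TRUE)
  files$demand_table <- dem_path

  json_path <- file.path(out_dir, "summary.json")
  summary_obj <- list(
    schema_version = bundle$schema_version,
    base_year = bundle$inputs$base_year,
    horizon = bundle$inputs$horizon,
    growth = list(
      census_years = bundle$growth$years,
      rates_total = report_rate(bundle$growth$rates$total),
      rates_65_plus = report_rate(bundle$growth$rates$age_65_plus),
      decrements = as.list(report_rate(bundle$growth$decrements))
    ),
    doubling_time_65_years = bundle$doubling_time_65,
    prevalence_percent = list(exact = bundle$prevalence$exact,
                              applied = bundle$prevalence$applied),
    comparisons = lapply(bundle$indices, function(x) {
      if (is.null(x$comparison)) NULL else list(
        H = x$comparison$omnibus_statistic, p = x$comparison$omnibus_p
      )
    }),
    scenario_table = as.data.frame(bundle$scenarios),
    demand_table = as.data.frame(bundle$demand)
  )
  jsonlite::write_json(summary_obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$summary_json <- json_path
  files
}

#' Run the pipeline on the published region-level inputs
#'
#' A packaged fixture exercising the whole pipeline on region-level numbers
#' only: the 2021 census totals (2,319,319 overall; 535,894 aged 65+), the
#' observed inter-census growth rates (total 0.49 then 0.19 %/yr; 65+ 1.69
#' then 1.40 %/yr, giving decrements of 0.30 and 0.29 pp/decade), and the
#' decade SAVR counts (1,538 in 2001-2011; 2,424 in 2011-2021). Because the
#' inputs are regional aggregates, no municipality-level index tables are
#' produced; the bundle carries the scenario projections to 2041, the demand
#' table, the 65+ doubling time and the 50-year (2071) constant-rate
#' projection.
#'
#' @param out_dir optional directory for report files
#' @param rounding_policy per-year increment reporting, see [demand_summary()]
#' @return a list bundle, analogous to [run_analysis()]
#' @examples
#' pm <- paper_mode()
#' pm$demand
#' @export
paper_mode <- function(out_dir = NULL, rounding_policy = "exact") {
  inputs <- list(
    base_year = 2021,
    p0_total = 2319319, p0_65plus = 535894,
    rates_total = c("2001-2011" = 0.49, "2011-2021" = 0.19),
    rates_65 = c("2001-2011" = 1.69, "2011-2021" = 1.40),
    registry = surgery_registry(c(2001, 2011), c(2011, 2021), c(1538, 2424))
  )
  base_rates <- c(total = unname(inputs$rates_total[2]),
                  age_65_plus = unname(inputs$rates_65[2]))
  decrements <- c(total = unname(diff(rev(inputs$rates_total))),
                  age_65_plus = unname(diff(rev(inputs$rates_65))))

  scen_tab <- scenario_table(inputs$p0_total, inputs$p0_65plus,
                             base_rates, decrements, base_year = 2021)

  dt65 <- doubling_time(base_rates[["age_65_plus"]])
  pop65_2071 <- project_population(inputs$p0_65plus,
                                   base_rates[["age_65_plus"]], 50,
                                   round = TRUE)

  last_dec <- inputs$registry[2, ]
  prev_exact <- decade_prevalence(last_dec$n_surgeries, inputs$p0_65plus)
  prev_applied <- report_rate(prev_exact)

  final <- scen_tab[scen_tab$stratum == "age_65_plus" & scen_tab$year == 2041 &
                      scen_tab$scenario != "census", , drop = FALSE]
  proj_pops <- stats::setNames(final$population, final$scenario)
  reference <- surgery_decade(2011, 2021, last_dec$n_surgeries)
  dem_tab <- demand_table(proj_pops, prev_applied, reference,
                          rounding_policy = rounding_policy)

  bundle <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    inputs = inputs,
    growth = list(base_rates = base_rates, decrements = decrements),
    doubling_time_65 = dt65,
    pop65_2071 = pop65_2071,
    scenarios = scen_tab,
    prevalence = list(exact = prev_exact, applied = prev_applied,
                      decade = c(2011, 2021)),
    demand = dem_tab,
    files = NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    scen_path <- file.path(out_dir, "scenario_table.csv")
    utils::write.csv(as.data.frame(scen_tab), scen_path, row.names = FALSE)
    dem_path <- file.path(out_dir, "demand_table.csv")
    utils::write.csv(as.data.frame(dem_tab), dem_path, row.names = FALSE)
    json_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(schema_version = REPORT_SCHEMA_VERSION,
           doubling_time_65_years = dt65, pop65_2071 = pop65_2071,
           prevalence_percent = prev_applied,
           scenario_table = as.data.frame(scen_tab),
           demand_table = as.data.frame(dem_tab)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    bundle$files <- list(scenario_table = scen_path, demand_table = dem_path,
                         summary_json = json_path)
  }
  bundle
}
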