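# Synthetic census panels and surgery registries with the statistical
# structure the pipeline assumes: log-normal municipality sizes (a few large
# municipalities dominate the regional aggregate), per-municipality geometric
# growth with Gaussian rate noise, age-structure shares drifting towards an
# older population, and decade surgery counts drawn Binomial(P_65_end, pi).

#' Configuration for the synthetic census generator
#'
#' Defaults emulate a referral region of 41 municipalities observed at the
#' 2001/2011/2021 census waves: log-normal municipality sizes totalling
#' roughly 2.3 million, total population growing ~0.35 %/yr and the elderly
#' ~1.5 %/yr with 0.5 pp municipality-level noise, a 2001 age structure of
#' 16% aged 0-14, 16.5% aged 65+ and 43% of the elderly aged 75+, and shares
#' drifting 2 pp older per decade.
#'
#' @param n_municipalities number of municipalities
#' @param census_years census waves (ascending)
#' @param base_pop_log_mean,base_pop_log_sd log-scale mean/sd of municipality
#'   total population at the first wave
#' @param growth_total,growth_65 mean annual growth of the total and the 65+
#'   population, percent/year
#' @param noise_sd municipality-level sd of both growth rates, percentage
#'   points
#' @param share_0_14_start,share_65_start first-wave shares of the 0-14 and
#'   65+ bands (fractions of total)
#' @param share_75_of_65_start first-wave share of the 65+ band aged 75+
#' @param share_sd municipality-level sd of the first-wave shares, so that
#'   age structure (and hence the indices) varies across municipalities
#' @param aging_drift per-decade drift applied to the shares: `share_0_14`
#'   falls and `share_75_of_65` rises by this amount each decade (fraction)
#' @param true_prevalence decade surgery prevalence used by
#'   [generate_registry()], percent
#' @param seed RNG seed; the seed fully determines the output
#' @return a list of class `synthetic_config`
#' @export
synthetic_config <- function(n_municipalities = 41,
                             census_years = c(2001, 2011, 2021),
                             base_pop_log_mean = 10.3,
                             base_pop_log_sd = 1.1,
                             growth_total = 0.35,
                             growth_65 = 1.5,
                             noise_sd = 0.5,
                             share_0_14_start = 0.16,
                             share_65_start = 0.165,
                             share_75_of_65_start = 0.43,
                             share_sd = 0.015,
                             aging_drift = 0.02,
                             true_prevalence = 0.45,
                             seed = 1L) {
  cfg <- list(
    n_municipalities = as.integer(n_municipalities),
    census_years = sort(as.integer(census_years)),
    base_pop_log_mean = base_pop_log_mean,
    base_pop_log_sd = base_pop_log_sd,
    growth_total = growth_total, growth_65 = growth_65,
    noise_sd = noise_sd,
    share_0_14_start = share_0_14_start,
    share_65_start = share_65_start,
    share_75_of_65_start = share_75_of_65_start,
    share_sd = share_sd,
    aging_drift = aging_drift,
    true_prevalence = true_prevalence,
    seed = as.integer(seed)
  )
  if (cfg$n_municipalities < 1) {
    stop_savr("savr_config_error", "need at least one municipality")
  }
  if (length(cfg$census_years) < 2) {
    stop_savr("savr_config_error", "need at least two census years")
  }
  shares <- c(cfg$share_0_14_start, cfg$share_65_start, cfg$share_75_of_65_start)
  if (any(shares <= 0) || any(shares >= 1)) {
    stop_savr("savr_config_error", "shares must lie strictly in (0, 1)")
  }
  if (cfg$share_0_14_start + cfg$share_65_start >= 0.95) {
    stop_savr("savr_config_error",
              "infeasible shares: 0-14 and 65+ leave no room for 15-64")
  }
  if (cfg$noise_sd < 0) stop_savr("savr_config_error", "noise_sd must be >= 0")
  if (cfg$share_sd < 0) stop_savr("savr_config_error", "share_sd must be >= 0")
  if (cfg$true_prevalence < 0 || cfg$true_prevalence > 100) {
    stop_savr("savr_config_error", "true_prevalence must be in [0, 100]")
  }
  structure(cfg, class = "synthetic_config")
}

clip_share <- function(x, lo = 0.001, hi = 0.999) pmin(hi, pmax(lo, x))

#' Generate a synthetic census panel
#'
#' Municipality total populations follow geometric growth at rate
#' `growth_total + N(0, noise_sd)` (drawn once per municipality); the 65+
#' band grows independently at `growth_65 + N(0, noise_sd)` from its
#' first-wave share; the 0-14 share falls and the 75+-of-65+ share rises by
#' `aging_drift` per decade (clipped to (0,1)). Band counts are rounded and
#' the residual is assigned to the 15-64 band so the partition invariant
#' holds exactly.
#'
#' @param config a [synthetic_config()]
#' @return a balanced [census_panel()]
#' @examples
#' generate_panel(synthetic_config(n_municipalities = 5, seed = 11))
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(cfg) {
  n <- cfg$n_municipalities
  muni <- sprintf("M%02d", seq_len(n))
  base_total <- pmax(500, round(stats::rlnorm(n, cfg$base_pop_log_mean,
                                              cfg$base_pop_log_sd)))
  g_tot <- cfg$growth_total + stats::rnorm(n, 0, cfg$noise_sd)
  g_65 <- cfg$growth_65 + stats::rnorm(n, 0, cfg$noise_sd)
  s014_0 <- clip_share(cfg$share_0_14_start + stats::rnorm(n, 0, cfg$share_sd),
                       lo = 0.02)
  s65_0 <- clip_share(cfg$share_65_start + stats::rnorm(n, 0, cfg$share_sd),
                      lo = 0.02)
  s75_0 <- clip_share(cfg$share_75_of_65_start + stats::rnorm(n, 0, cfg$share_sd))
  base_65 <- s65_0 * base_total

  rows <- lapply(cfg$census_years, function(y) {
    dt <- y - cfg$census_years[1]
    decades <- dt / 10
    s014 <- clip_share(s014_0 - cfg$aging_drift * decades)
    s75 <- clip_share(s75_0 + cfg$aging_drift * decades)
    pop_total <- round_half_up(base_total * (1 + g_tot / 100)^dt)
    pop_65 <- round_half_up(base_65 * (1 + g_65 / 100)^dt)
    pop_0_14 <- round_half_up(s014 * pop_total)
    pop_65 <- pmin(pop_65, pop_total - pop_0_14)
    pop_75 <- pmin(round_half_up(s75 * pop_65), pop_65)
    pop_15_64 <- pop_total - pop_0_14 - pop_65
    if (any(pop_15_64 < 0)) {
      stop_savr("savr_config_error",
                "infeasible configuration: 15-64 band went negative")
    }
    tibble::tibble(
      municipality = muni, year = y, sex = "all",
      pop_total = pop_total, pop_0_14 = pop_0_14, pop_15_64 = pop_15_64,
      pop_65_plus = pop_65, pop_75_plus = pop_75
    )
  })
  census_panel(do.call(rbind, rows))
}

#' Generate a synthetic surgery registry from a census panel
#'
#' For each pair of consecutive census waves (which must be 10 years apart),
#' draws the decade SAVR count as
#' `Binomial(regional 65+ population at the decade's end, true_prevalence/100)`.
#'
#' @param panel a [census_panel()] with 10-year wave spacing
#' @param true_prevalence decade prevalence in percent
#' @param seed RNG seed
#' @return a `surgery_registry` (see [surgery_registry()])
#' @examples
#' p <- generate_panel(synthetic_config(seed = 5))
#' generate_registry(p, 0.45, seed = 5)
#' @export
generate_registry <- function(panel, true_prevalence = 0.45, seed = 1L) {
  years <- panel_years(panel)
  if (length(years) < 2 || any(diff(years) != 10)) {
    stop_savr("savr_config_error",
              "registry generation needs census waves spaced exactly 10 years")
  }
  if (true_prevalence < 0 || true_prevalence > 100) {
    stop_savr("savr_config_error", "true_prevalence must be in [0, 100]")
  }
  pops_end <- vapply(years[-1], function(y) {
    aggregate_region(panel, "all", y)$pop_65_plus
  }, numeric(1))
  withr::with_seed(as.integer(seed), {
    s <- stats::rbinom(length(pops_end), size = as.integer(pops_end),
                       prob = true_prevalence / 100)
    surgery_registry(
      start_year = years[-length(years)], end_year = years[-1],
      n_surgeries = s
    )
  })
}
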