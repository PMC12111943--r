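# Small deterministic fixtures built in code.

# A hand-written balanced 3-municipality x 3-wave panel with known counts.
tiny_panel <- function() {
  rows <- expand.grid(
    municipality = c("Alfa", "Beta", "Gama"),
    year = c(2001, 2011, 2021),
    stringsAsFactors = FALSE
  )
  base <- c(Alfa = 10000, Beta = 50000, Gama = 200000)
  rows$pop_total <- unname(base[rows$municipality]) + 100 * (rows$year - 2001)
  rows$pop_0_14 <- round(0.15 * rows$pop_total) - 10 * (rows$year - 2001) / 10
  rows$pop_65_plus <- round(0.18 * rows$pop_total) + 20 * (rows$year - 2001) / 10
  rows$pop_15_64 <- rows$pop_total - rows$pop_0_14 - rows$pop_65_plus
  rows$pop_75_plus <- round(0.45 * rows$pop_65_plus)
  rows$sex <- "all"
  census_panel(rows)
}

# A panel with female/male strata whose 2001 male total matches the published
# regional male count, alongside consistent all-sex rows.
sex_panel <- function() {
  mk <- function(sex, year, total) {
    p014 <- round(0.15 * total)
    p65 <- round(0.2 * total)
    census_record("Region", year, total, p014, total - p014 - p65, p65,
                  round(0.45 * p65), sex = sex)
  }
  census_panel(rbind(
    mk("male", 2001, 1042214), mk("female", 2001, 1125005),
    mk("all", 2001, 1042214 + 1125005),
    mk("male", 2021, 1103886), mk("female", 2021, 1215430),
    mk("all", 2021, 1103886 + 1215430)
  ))
}

# Random feasible generator configuration for property-style loops.
random_config <- function(seed) {
  withr::with_seed(seed, {
    synthetic_config(
      n_municipalities = sample(1:8, 1),
      census_years = c(2001, 2011, 2021),
      base_pop_log_mean = runif(1, 7, 10),
      base_pop_log_sd = runif(1, 0.3, 1.2),
      growth_total = runif(1, -1, 1),
      growth_65 = runif(1, 0, 2.5),
      noise_sd = runif(1, 0, 1),
      share_0_14_start = runif(1, 0.10, 0.22),
      share_65_start = runif(1, 0.10, 0.25),
      share_75_of_65_start = runif(1, 0.30, 0.55),
      share_sd = runif(1, 0, 0.02),
      aging_drift = runif(1, 0, 0.04),
      seed = seed
    )
  })
}
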