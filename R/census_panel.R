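#' Construct a single census record
#'
#' A census record is one municipality in one census year (optionally one sex
#' stratum) with its age-band population counts. Age bands follow the standard
#' demographic breakdown: 0-14 (youth), 15-64 (working age), 65+ (elderly),
#' with the 75+ sub-band of the elderly optionally available (it is needed for
#' the longevity index but some census extracts omit it).
#'
#' Invariants enforced: all counts are non-negative integers; when all three
#' broad bands are present they must sum exactly to the total; the 75+ count
#' can never exceed the 65+ count.
#'
#' @param municipality municipality identifier (opaque string key)
#' @param year census year, e.g. 2001
#' @param pop_total total resident population
#' @param pop_0_14,pop_15_64,pop_65_plus broad age-band counts
#' @param pop_75_plus count aged 75 and over, or `NA` if the extract lacks it
#' @param sex one of `"all"`, `"female"`, `"male"`
#' @return a one-row tibble of class `census_record`
#' @examples
#' census_record("Lisboa", 2021, 100, 20, 60, 20, 10)
#' @export
census_record <- function(municipality, year, pop_total, pop_0_14, pop_15_64,
                          pop_65_plus, pop_75_plus = NA, sex = "all") {
  rec <- tibble::tibble(
    municipality = as.character(municipality),
    year = as.integer(year),
    sex = as.character(sex),
    pop_total = as.numeric(pop_total),
    pop_0_14 = as.numeric(pop_0_14),
    pop_15_64 = as.numeric(pop_15_64),
    pop_65_plus = as.numeric(pop_65_plus),
    pop_75_plus = as.numeric(pop_75_plus)
  )
  validate_census_records(rec)
  class(rec) <- c("census_record", class(rec))
  rec
}

census_columns <- c(
  "municipality", "year", "sex", "pop_total",
  "pop_0_14", "pop_15_64", "pop_65_plus", "pop_75_plus"
)

# Per-record invariant checks. Validation is within a record: sex strata are
# never cross-checked against each other, so source inconsistencies between
# printed sex totals and all-sex totals pass through untouched.
validate_census_records <- function(df) {
  counts <- c("pop_total", "pop_0_14", "pop_15_64", "pop_65_plus", "pop_75_plus")
  for (col in counts) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < 0 | v != floor(v))
    if (any(bad)) {
      stop_savr("savr_validation_error", sprintf(
        "column %s has negative or non-integer counts (e.g. %s, %s)",
        col, df$municipality[bad][1], df$year[bad][1]
      ))
    }
    if (col != "pop_75_plus" && anyNA(v)) {
      stop_savr("savr_validation_error",
                sprintf("column %s has missing values", col))
    }
  }
  band_sum <- df$pop_0_14 + df$pop_15_64 + df$pop_65_plus
  bad <- band_sum != df$pop_total
  if (any(bad)) {
    stop_savr("savr_validation_error", sprintf(
      "age bands do not sum to pop_total for %s, %d (bands %d vs total %d)",
      df$municipality[bad][1], df$year[bad][1],
      band_sum[bad][1], df$pop_total[bad][1]
    ))
  }
  bad <- !is.na(df$pop_75_plus) & df$pop_75_plus > df$pop_65_plus
  if (any(bad)) {
    stop_savr("savr_validation_error", sprintf(
      "pop_75_plus exceeds pop_65_plus for %s, %d",
      df$municipality[bad][1], df$year[bad][1]
    ))
  }
  bad_sex <- !df$sex %in% c("all", "female", "male")
  if (any(bad_sex)) {
    stop_savr("savr_validation_error", sprintf(
      "sex must be one of all/female/male, got '%s'", df$sex[bad_sex][1]
    ))
  }
  invisible(df)
}

#' Construct a census panel
#'
#' A census panel collects census records across municipalities and census
#' waves. Keys `(municipality, year, sex)` must be unique. The panel is
#' *balanced* when, within each sex stratum, every municipality appears in
#' every census year; an unbalanced panel is accepted but flagged via the
#' `complete` attribute (and rejected when `require_balanced = TRUE`).
#'
#' @param records data frame with columns `municipality`, `year`, `sex`,
#'   `pop_total`, `pop_0_14`, `pop_15_64`, `pop_65_plus`, `pop_75_plus`
#'   (`sex` defaults to "all" and `pop_75_plus` to `NA` when absent)
#' @param require_balanced error on an unbalanced panel?
#' @return a tibble of class `census_panel` with attribute `complete`
#' @seealso [read_census_csv()], [aggregate_region()]
#' @export
census_panel <- function(records, require_balanced = FALSE) {
  df <- tibble::as_tibble(as.data.frame(records, stringsAsFactors = FALSE))
  if (!"sex" %in% names(df)) df$sex <- "all"
  if (!"pop_75_plus" %in% names(df)) df$pop_75_plus <- NA_real_
  missing_cols <- setdiff(census_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_savr("savr_schema_error", sprintf(
      "missing required column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  df <- df[census_columns]
  df$municipality <- as.character(df$municipality)
  df$year <- as.integer(df$year)
  df$sex <- as.character(df$sex)
  for (col in c("pop_total", "pop_0_14", "pop_15_64", "pop_65_plus", "pop_75_plus")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_census_records(df)

  key <- paste(df$municipality, df$year, df$sex, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop_savr("savr_validation_error", sprintf(
      "duplicate (municipality, year, sex) key: %s, %d, %s",
      dup$municipality[1], dup$year[1], dup$sex[1]
    ))
  }

  complete <- all(vapply(split(df, df$sex), function(stratum) {
    tab <- table(stratum$municipality, stratum$year)
    all(tab == 1) &&
      nrow(tab) == length(unique(df$municipality[df$sex == stratum$sex[1]]))
  }, logical(1)))
  if (require_balanced && !complete) {
    stop_savr("savr_validation_error",
              "panel is unbalanced: not every municipality appears in every year")
  }

  df <- df[order(df$municipality, df$year, df$sex), ]
  df <- tibble::as_tibble(as.list(df)) # drop any stray attributes
  structure(df, class = c("census_panel", class(tibble::tibble())),
            complete = complete)
}

#' @export
print.census_panel <- function(x, ...) {
  cat(sprintf(
    "<census_panel> %d municipalities x %d census years (%s)%s\n",
    length(unique(x$municipality)), length(unique(x$year)),
    paste(sort(unique(x$year)), collapse = ", "),
    if (isTRUE(attr(x, "complete"))) "" else " [unbalanced]"
  ))
  NextMethod()
}

#' Census years present in a panel
#' @param panel a [census_panel()]
#' @return sorted integer vector of census years
#' @export
panel_years <- function(panel) sort(unique(panel$year))

#' Municipalities present in a panel
#' @param panel a [census_panel()]
#' @return sorted character vector of municipality keys
#' @export
panel_municipalities <- function(panel) sort(unique(panel$municipality))

#' Aggregate municipalities to a regional census record
#'
#' Sums every age-band count over the requested municipalities for one census
#' year (and sex stratum), e.g. to obtain the referral-region total from its
#' member municipalities. Summation preserves all record invariants; the 75+
#' total is `NA` if any member lacks it.
#'
#' @param panel a [census_panel()]
#' @param municipalities character vector of municipality keys, or `"all"`
#' @param year census year to aggregate
#' @param sex sex stratum to aggregate within (default `"all"`)
#' @param name identifier given to the aggregated record
#' @return a one-row `census_record`
#' @examples
#' p <- generate_panel(synthetic_config(n_municipalities = 5, seed = 1))
#' aggregate_region(p, "all", 2021)
#' @export
aggregate_region <- function(panel, municipalities = "all", year, sex = "all",
                             name = "region") {
  if (identical(municipalities, "all")) {
    municipalities <- unique(panel$municipality)
  }
  sub <- panel[panel$year == year & panel$sex == sex &
                 panel$municipality %in% municipalities, , drop = FALSE]
  missing <- setdiff(municipalities, sub$municipality)
  if (length(missing) > 0) {
    stop_savr("savr_lookup_error", sprintf(
      "no record for municipality '%s' in year %d (sex %s)",
      missing[1], as.integer(year), sex
    ))
  }
  p75 <- if (anyNA(sub$pop_75_plus)) NA else sum(sub$pop_75_plus)
  census_record(
    municipality = name, year = year, sex = sex,
    pop_total = sum(sub$pop_total), pop_0_14 = sum(sub$pop_0_14),
    pop_15_64 = sum(sub$pop_15_64), pop_65_plus = sum(sub$pop_65_plus),
    pop_75_plus = p75
  )
}

#' Pyramid-style age-band summary for one census year
#'
#' Tabulates regional population counts by age band and sex for one census
#' wave, the numbers underlying a population pyramid. Band schemes:
#' `"broad"` (0-14 / 15-64 / 65+), `"elderly_split"` (0-14 / 15-64 / 65-74 /
#' 75+; requires the 75+ column), or `"total"` (a single all-ages band).
#' Within each sex stratum the band counts partition the total population.
#'
#' @param panel a [census_panel()]
#' @param year census year
#' @param bands band scheme, see above
#' @param by_sex tabulate female/male separately? Requires sex-stratified
#'   records in the panel.
#' @return tibble with columns `band`, `sex`, `count`
#' @export
pyramid_summary <- function(panel, year,
                            bands = c("broad", "elderly_split", "total"),
                            by_sex = FALSE) {
  bands <- match.arg(bands)
  sexes <- if (by_sex) c("female", "male") else "all"
  have <- unique(panel$sex[panel$year == year])
  if (!all(sexes %in% have)) {
    stop_savr("savr_capability_error", sprintf(
      "panel has no %s records for year %d",
      paste(setdiff(sexes, have), collapse = "/"), as.integer(year)
    ))
  }
  rows <- lapply(sexes, function(s) {
    reg <- aggregate_region(panel, "all", year, sex = s)
    counts <- switch(bands,
      total = c("all ages" = reg$pop_total),
      broad = c("0-14" = reg$pop_0_14, "15-64" = reg$pop_15_64,
                "65+" = reg$pop_65_plus),
      elderly_split = {
        if (is.na(reg$pop_75_plus)) {
          stop_savr("savr_capability_error",
                    "elderly_split bands require the 75+ column")
        }
        c("0-14" = reg$pop_0_14, "15-64" = reg$pop_15_64,
          "65-74" = reg$pop_65_plus - reg$pop_75_plus,
          "75+" = reg$pop_75_plus)
      }
    )
    tibble::tibble(band = names(counts), sex = s, count = unname(counts))
  })
  do.call(rbind, rows)
}
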