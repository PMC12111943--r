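# CSV I/O for census panels and surgery registries.
#
# Census CSV schema (UTF-8, header required):
#   municipality,year,sex,pop_total,pop_0_14,pop_15_64,pop_65_plus,pop_75_plus
# `sex` and `pop_75_plus` are optional columns. Counts accept plain integers
# and "," thousands separators ("1,042,214"); decimals are rejected.

#' Read a municipality census panel from CSV
#'
#' @param path path to a CSV file following the schema above
#' @param require_balanced reject panels where some municipality is missing
#'   from some census year?
#' @return a validated [census_panel()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_census_csv(generate_panel(synthetic_config(n_municipalities = 3,
#'                                                  seed = 7)), f)
#' read_census_csv(f)
#' @export
read_census_csv <- function(path, require_balanced = FALSE) {
  if (!file.exists(path)) {
    stop_savr("savr_schema_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE, fileEncoding = "UTF-8")
  required <- c("municipality", "year", "pop_total", "pop_0_14",
                "pop_15_64", "pop_65_plus")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_savr("savr_schema_error", sprintf(
      "census CSV is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  df <- tibble::tibble(
    municipality = raw$municipality,
    year = as.integer(parse_count(raw$year, "year")),
    sex = if ("sex" %in% names(raw)) raw$sex else "all",
    pop_total = parse_count(raw$pop_total, "pop_total"),
    pop_0_14 = parse_count(raw$pop_0_14, "pop_0_14"),
    pop_15_64 = parse_count(raw$pop_15_64, "pop_15_64"),
    pop_65_plus = parse_count(raw$pop_65_plus, "pop_65_plus"),
    pop_75_plus = if ("pop_75_plus" %in% names(raw)) {
      parse_count(raw$pop_75_plus, "pop_75_plus")
    } else {
      NA_real_
    }
  )
  census_panel(df, require_balanced = require_balanced)
}

#' Write a census panel to CSV
#'
#' Writes the schema accepted by [read_census_csv()]; a write/read round trip
#' reproduces the panel exactly. Counts are written without thousands
#' separators.
#'
#' @param panel a [census_panel()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_census_csv <- function(panel, path) {
  df <- as.data.frame(panel)[census_columns]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_savr("savr_schema_error", sprintf("cannot write to %s", path))
  invisible(path)
}

#' Read a surgery registry from CSV
#'
#' Registry schema: `start_year,end_year,n_surgeries`, one row per decade of
#' surgical aortic valve replacements in patients aged 65 and over.
#'
#' @param path path to the registry CSV
#' @return a `surgery_registry` tibble (see [surgery_decade()])
#' @export
read_registry_csv <- function(path) {
  if (!file.exists(path)) {
    stop_savr("savr_schema_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  missing_cols <- setdiff(c("start_year", "end_year", "n_surgeries"), names(raw))
  if (length(missing_cols) > 0) {
    stop_savr("savr_schema_error", sprintf(
      "registry CSV is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  surgery_registry(
    start_year = as.integer(parse_count(raw$start_year, "start_year")),
    end_year = as.integer(parse_count(raw$end_year, "end_year")),
    n_surgeries = parse_count(raw$n_surgeries, "n_surgeries")
  )
}

#' Write a surgery registry to CSV
#'
#' @param registry a `surgery_registry`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_registry_csv <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
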