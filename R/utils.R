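# Shared helpers: classed conditions, integer parsing, report rounding.
# All report-time rounding lives here so chained computations never round
# intermediates.

stop_savr <- function(class, message, call = NULL) {
  cond <- structure(
    class = c(class, "savr_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

#' Round to the nearest integer, halves away from zero
#'
#' Person and surgery counts are reported with conventional half-up rounding
#' rather than IEEE round-half-even, so that e.g. 2424.5 reports as 2425.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# report scales: persons/surgeries -> integer, indices -> 1 dp,
# rates/prevalences -> 2 dp
report_persons <- function(x) round_half_up(x)
report_index   <- function(x) round(x, 1)
report_rate    <- function(x) round(x, 2)

#' Parse census counts
#'
#' Accepts plain integers ("1042214") and comma thousands separators
#' ("1,042,214"). Decimal values are rejected: census counts are persons.
#'
#' @param x character or numeric vector
#' @param what label used in error messages
#' @return numeric vector of non-negative integers (NA preserved)
#' @keywords internal
parse_count <- function(x, what = "count") {
  if (is.numeric(x)) {
    out <- x
  } else {
    x <- trimws(as.character(x))
    x[x == ""] <- NA_character_
    bad_fmt <- !is.na(x) & !grepl("^[0-9]{1,3}(,[0-9]{3})*$|^[0-9]+$", x)
    if (any(bad_fmt)) {
      stop_savr("savr_schema_error", sprintf(
        "%s value(s) not a non-negative integer count: %s",
        what, paste(utils::head(x[bad_fmt], 3), collapse = ", ")
      ))
    }
    out <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  }
  ok <- is.na(out) | (out >= 0 & out == floor(out))
  if (!all(ok)) {
    stop_savr("savr_schema_error", sprintf(
      "%s value(s) not a non-negative integer count: %s",
      what, paste(utils::head(out[!ok], 3), collapse = ", ")
    ))
  }
  out
}
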