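#' Aging index
#'
#' The aging index compares the elderly to the youth population:
#' \deqn{AI = 100 \times P_{65+} / P_{0\mbox{-}14}.}
#' A value above 100 means more elderly than young people. It is undefined
#' when there is no youth population (an error, not infinity).
#'
#' @param pop_65_plus persons aged 65 and over
#' @param pop_0_14 persons aged 0 to 14 (must be positive)
#' @return the index on the per-100 scale, full precision (round to 1 decimal
#'   for reporting)
#' @examples
#' aging_index(200, 100) # 200: twice as many elderly as young
#' @export
aging_index <- function(pop_65_plus, pop_0_14) {
  if (any(is.na(pop_65_plus)) || any(is.na(pop_0_14))) {
    stop_savr("savr_domain_error", "aging index inputs must not be missing")
  }
  if (any(pop_0_14 <= 0)) {
    stop_savr("savr_undefined_index_error",
              "aging index undefined: youth population (0-14) is zero")
  }
  100 * pop_65_plus / pop_0_14
}

#' Longevity index
#'
#' The longevity index is the share (per 100) of the elderly population that
#' is very old:
#' \deqn{LI = 100 \times P_{75+} / P_{65+}.}
#' It measures aging *within* the elderly and is bounded in \[0, 100\].
#'
#' @param pop_75_plus persons aged 75 and over
#' @param pop_65_plus persons aged 65 and over (must be positive)
#' @return the index on the per-100 scale, full precision
#' @examples
#' longevity_index(50, 100) # half of the elderly are 75+
#' @export
longevity_index <- function(pop_75_plus, pop_65_plus) {
  if (any(is.na(pop_75_plus)) || any(is.na(pop_65_plus))) {
    stop_savr("savr_domain_error", "longevity index inputs must not be missing")
  }
  if (any(pop_65_plus <= 0)) {
    stop_savr("savr_undefined_index_error",
              "longevity index undefined: elderly population (65+) is zero")
  }
  if (any(pop_75_plus > pop_65_plus)) {
    stop_savr("savr_validation_error",
              "pop_75_plus cannot exceed pop_65_plus")
  }
  100 * pop_75_plus / pop_65_plus
}

#' Aging or longevity index for every municipality and census year
#'
#' Computes the chosen index for each `(municipality, year)` cell of a panel
#' (all-sex stratum). Municipalities where the index is undefined (zero
#' denominator) are kept and flagged via the `undefined` column rather than
#' silently dropped; their `value` is `NA` and they are excluded from the
#' per-year summaries.
#'
#' @param panel a [census_panel()]
#' @param index `"aging"` or `"longevity"`
#' @param range how the per-year spread is summarised alongside the median:
#'   `"minmax"` (default) or `"iqr"`
#' @return a tibble of class `index_table` with columns `index`,
#'   `municipality`, `year`, `value`, `undefined`; per-year summaries via
#'   [summary()] / [index_summary()]
#' @examples
#' p <- generate_panel(synthetic_config(seed = 42))
#' tab <- index_table(p, "aging")
#' summary(tab)
#' @export
index_table <- function(panel, index = c("aging", "longevity"),
                        range = c("minmax", "iqr")) {
  index <- match.arg(index)
  range <- match.arg(range)
  sub <- panel[panel$sex == "all", , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_savr("savr_capability_error", "panel has no all-sex records")
  }
  if (index == "longevity" && anyNA(sub$pop_75_plus)) {
    stop_savr("savr_capability_error",
              "longevity index requires the 75+ column for every record")
  }
  if (index == "aging") {
    undef <- sub$pop_0_14 <= 0
    value <- ifelse(undef, NA_real_, 100 * sub$pop_65_plus / sub$pop_0_14)
  } else {
    undef <- sub$pop_65_plus <= 0
    value <- ifelse(undef, NA_real_, 100 * sub$pop_75_plus / sub$pop_65_plus)
  }
  out <- tibble::tibble(
    index = index, municipality = sub$municipality, year = sub$year,
    value = value, undefined = undef
  )
  structure(out, class = c("index_table", class(tibble::tibble())),
            index_name = index, range_type = range)
}

#' Per-year summary of an index table
#'
#' Median and spread of the index across municipalities for each census year,
#' in the `median (low-high)` style customary for skewed demographic
#' indicators. The spread is the min-max range or the interquartile range
#' according to the table's `range` setting.
#'
#' @param table an [index_table()]
#' @return tibble with columns `index`, `year`, `median`, `low`, `high`, `n`
#' @export
index_summary <- function(table) {
  range_type <- attr(table, "range_type")
  years <- sort(unique(table$year))
  rows <- lapply(years, function(y) {
    v <- table$value[table$year == y & !table$undefined]
    spread <- if (identical(range_type, "iqr")) {
      stats::quantile(v, c(0.25, 0.75), names = FALSE)
    } else {
      range(v)
    }
    tibble::tibble(
      index = attr(table, "index_name"), year = y,
      median = stats::median(v), low = spread[1], high = spread[2],
      n = length(v)
    )
  })
  do.call(rbind, rows)
}

#' @export
summary.index_table <- function(object, ...) index_summary(object)

#' @export
print.index_table <- function(x, ...) {
  cat(sprintf("<index_table: %s index, %s range>\n",
              attr(x, "index_name"), attr(x, "range_type")))
  NextMethod()
}

#' Count municipalities below an index threshold
#'
#' @param table an [index_table()]
#' @param year census year
#' @param threshold index cutoff (default 100, the parity line of the aging
#'   index)
#' @return number of municipalities with a defined index strictly below the
#'   threshold in that year
#' @export
count_below <- function(table, year, threshold = 100) {
  v <- table$value[table$year == year & !table$undefined]
  sum(v < threshold)
}

#' Compare index distributions across census years
#'
#' Omnibus Kruskal-Wallis rank test (with the standard tie correction) for a
#' shift in the index distribution across census years, followed by Dunn's
#' pairwise z-tests on mean ranks with Bonferroni adjustment. Dunn's test uses
#' the large-sample normal approximation with tie-corrected variance and
#' two-sided p-values; adjusted p-values are capped at 1.
#'
#' @param table an [index_table()] with at least two years, each contributing
#'   at least two defined values
#' @return a list of class `year_comparison` with elements
#'   `omnibus_statistic` (Kruskal-Wallis H), `omnibus_df`, `omnibus_p`, and
#'   `pairwise`, a tibble of `(year_a, year_b, z, p_value, adjusted_p)`
#' @examples
#' p <- generate_panel(synthetic_config(seed = 3))
#' compare_years(index_table(p, "aging"))
#' @export
compare_years <- function(table) {
  ok <- !table$undefined & !is.na(table$value)
  values <- table$value[ok]
  years <- factor(table$year[ok])
  sizes <- table(years)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop_savr("savr_insufficient_data_error",
              "need >= 2 years with >= 2 index values each")
  }
  if (stats::var(values) == 0) {
    # every observation tied: no between-year variation by construction
    lev <- levels(years)
    pairs <- utils::combn(seq_along(lev), 2)
    pairwise <- tibble::tibble(
      year_a = lev[pairs[1, ]], year_b = lev[pairs[2, ]],
      z = 0, p_value = 1, adjusted_p = 1
    )
    H <- 0; df <- length(lev) - 1L; p <- 1
  } else {
    kw <- stats::kruskal.test(values, years)
    H <- unname(kw$statistic); df <- unname(kw$parameter); p <- kw$p.value
    pairwise <- dunn_test(values, years)
  }
  structure(
    list(
      omnibus_statistic = H,
      omnibus_df = df,
      omnibus_p = p,
      pairwise = pairwise
    ),
    class = "year_comparison"
  )
}

# Dunn's multiple-comparison z statistics on mean ranks, with tie correction
# Sigma(t^3 - t) / (12 (N - 1)) subtracted from the null variance
# N (N + 1) / 12, and Bonferroni multiplication over all C(k, 2) pairs.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n_tot <- length(values)
  mean_ranks <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  m <- ncol(pairs)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z[k] <- (mean_ranks[i] - mean_ranks[j]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  tibble::tibble(
    year_a = lev[pairs[1, ]], year_b = lev[pairs[2, ]],
    z = z, p_value = p, adjusted_p = pmin(1, p * m)
  )
}

#' @export
print.year_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$omnibus_statistic, x$omnibus_df, x$omnibus_p))
  cat("Dunn pairwise comparisons (Bonferroni-adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

#' Write the tidy index CSVs
#'
#' Emits the per-municipality values (`index,municipality,year,value`) and the
#' per-year summary (`index,year,median,low,high,n`).
#'
#' @param table an [index_table()]
#' @param values_path,summary_path output CSV paths (either may be `NULL` to
#'   skip)
#' @return invisibly, a list with the written paths
#' @export
write_index_csv <- function(table, values_path = NULL, summary_path = NULL) {
  if (!is.null(values_path)) {
    utils::write.csv(
      as.data.frame(table)[c("index", "municipality", "year", "value")],
      values_path, row.names = FALSE, quote = TRUE, na = ""
    )
  }
  if (!is.null(summary_path)) {
    utils::write.csv(as.data.frame(index_summary(table)), summary_path,
                     row.names = FALSE, quote = TRUE)
  }
  invisible(list(values = values_path, summary = summary_path))
}
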