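test_that("aging and longevity indices match the per-100 ratio definition", {
  expect_equal(aging_index(100, 100), 100)
  expect_equal(aging_index(200, 100), 200)
  expect_equal(longevity_index(50, 100), 50)
  expect_equal(longevity_index(0, 100), 0)

  withr::with_seed(11, {
    for (i in 1:50) {
      a <- sample(0:5e5, 1); b <- sample(1:5e5, 1)
      expect_equal(aging_index(a, b), 100 * a / b, tolerance = 1e-12)
      p65 <- sample(1:5e5, 1); p75 <- sample(0:p65, 1)
      expect_equal(longevity_index(p75, p65), 100 * p75 / p65,
                   tolerance = 1e-12)
    }
  })
})

test_that("undefined indices error instead of returning infinity", {
  expect_error(aging_index(10, 0), class = "savr_undefined_index_error")
  expect_error(longevity_index(10, 0), class = "savr_undefined_index_error")
  expect_error(longevity_index(20, 10), class = "savr_validation_error")
})

test_that("indices are scale-equivariant and monotone in the elderly count", {
  withr::with_seed(21, {
    for (i in 1:25) {
      p014 <- sample(100:10000, 1)
      p65 <- sample(100:10000, 1)
      p75 <- sample(0:p65, 1)
      k <- sample(2:50, 1)
      expect_equal(aging_index(k * p65, k * p014), aging_index(p65, p014))
      expect_equal(longevity_index(k * p75, k * p65), longevity_index(p75, p65))
      # more elderly: aging index up, longevity index down (75+ fixed)
      expect_gt(aging_index(p65 + 1, p014), aging_index(p65, p014))
      expect_lt(longevity_index(p75, p65 + 1), longevity_index(p75, p65))
    }
  })
})

test_that("index tables flag undefined cells and summarise by year correctly", {
  p <- tiny_panel()
  one <- index_table(census_panel(p[p$municipality == "Alfa" & p$year == 2001, ]),
                     "aging")
  expect_equal(nrow(one), 1)
  expect_equal(index_summary(one)$median, one$value)

  tab <- index_table(generate_panel(synthetic_config(seed = 31)), "aging")
  df <- as.data.frame(tab)
  for (y in unique(df$year)) {
    v <- df$value[df$year == y]
    s <- index_summary(tab)
    expect_equal(s$median[s$year == y], median(v))
    expect_equal(s$low[s$year == y], min(v))
    expect_equal(s$high[s$year == y], max(v))
  }
  # IQR variant
  tab_iqr <- index_table(generate_panel(synthetic_config(seed = 31)), "aging",
                         range = "iqr")
  s <- index_summary(tab_iqr)
  v <- df$value[df$year == 2011]
  expect_equal(s$low[s$year == 2011], unname(quantile(v, 0.25)))

  # below-threshold counts match a brute-force count
  expect_equal(count_below(tab, 2001, 100), sum(df$value[df$year == 2001] < 100))

  # a zero-youth municipality is flagged, not dropped
  odd <- census_panel(rbind(
    data.frame(municipality = "A", year = 2001, sex = "all", pop_total = 100,
               pop_0_14 = 0, pop_15_64 = 60, pop_65_plus = 40, pop_75_plus = 10),
    data.frame(municipality = "B", year = 2001, sex = "all", pop_total = 100,
               pop_0_14 = 20, pop_15_64 = 60, pop_65_plus = 20, pop_75_plus = 10)
  ))
  t2 <- index_table(odd, "aging")
  expect_equal(nrow(t2), 2)
  expect_true(t2$undefined[t2$municipality == "A"])
  expect_true(is.na(t2$value[t2$municipality == "A"]))
  expect_equal(index_summary(t2)$n, 1)

  expect_error(index_table(census_panel(transform(as.data.frame(p),
                                                  pop_75_plus = NA)),
                           "longevity"),
               class = "savr_capability_error")
})

test_that("Kruskal-Wallis and Dunn match a brute-force rank oracle", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  yrs <- rep(c(2001, 2011, 2021), each = 3)
  tab <- structure(
    tibble::tibble(index = "aging", municipality = rep(c("A", "B", "C"), 3),
                   year = yrs, value = vals, undefined = FALSE),
    class = c("index_table", class(tibble::tibble())),
    index_name = "aging", range_type = "minmax"
  )
  res <- compare_years(tab)

  # brute force: ranks are 1..9, rank sums 6, 15, 24 (no ties)
  r <- rank(vals)
  rs <- tapply(r, yrs, sum)
  H_oracle <- 12 / (9 * 10) * sum(rs^2 / 3) - 3 * 10
  expect_equal(H_oracle, 7.2)
  expect_equal(res$omnibus_statistic, H_oracle, tolerance = 1e-12)
  expect_equal(res$omnibus_p, pchisq(7.2, 2, lower.tail = FALSE))

  # Dunn oracle: mean ranks 2/5/8, null variance N(N+1)/12, Bonferroni x3
  se <- sqrt(9 * 10 / 12 * (1 / 3 + 1 / 3))
  z_oracle <- (2 - 5) / se
  p_oracle <- 2 * pnorm(-abs(z_oracle))
  row <- res$pairwise[res$pairwise$year_a == "2001" &
                        res$pairwise$year_b == "2011", ]
  expect_equal(row$z, z_oracle, tolerance = 1e-12)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(row$adjusted_p, min(1, 3 * p_oracle), tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), choose(3, 2))
  expect_true(all(res$pairwise$adjusted_p >= 0 & res$pairwise$adjusted_p <= 1))
})

test_that("tied data use the tie-corrected H and Dunn variance", {
  vals <- c(1, 2, 2, 2, 3, 4, 4, 5, 6)
  yrs <- rep(c(2001, 2011, 2021), each = 3)
  tab <- structure(
    tibble::tibble(index = "aging", municipality = rep(c("A", "B", "C"), 3),
                   year = yrs, value = vals, undefined = FALSE),
    class = c("index_table", class(tibble::tibble())),
    index_name = "aging", range_type = "minmax"
  )
  res <- compare_years(tab)

  r <- rank(vals)
  rs <- tapply(r, yrs, sum)
  n_tot <- 9
  H_raw <- 12 / (n_tot * (n_tot + 1)) * sum(rs^2 / 3) - 3 * (n_tot + 1)
  ties <- table(vals)
  correction <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  expect_equal(res$omnibus_statistic, H_raw / correction, tolerance = 1e-12)

  tie_term <- sum(table(r)^3 - table(r)) / (12 * (n_tot - 1))
  se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) * (2 / 3))
  mean_ranks <- tapply(r, yrs, mean)
  z_oracle <- (mean_ranks[["2001"]] - mean_ranks[["2021"]]) / se
  row <- res$pairwise[res$pairwise$year_b == "2021" &
                        res$pairwise$year_a == "2001", ]
  expect_equal(row$z, unname(z_oracle), tolerance = 1e-12)
})

test_that("identical year distributions give H = 0 and p = 1", {
  tab <- structure(
    tibble::tibble(index = "aging", municipality = rep(c("A", "B", "C"), 3),
                   year = rep(c(2001, 2011, 2021), each = 3),
                   value = rep(c(1, 2, 3), 3), undefined = FALSE),
    class = c("index_table", class(tibble::tibble())),
    index_name = "aging", range_type = "minmax"
  )
  res <- compare_years(tab)
  expect_equal(res$omnibus_statistic, 0, tolerance = 1e-12)
  expect_equal(res$omnibus_p, 1)

  # fully degenerate case: every value equal
  tab$value <- 1
  res2 <- compare_years(tab)
  expect_equal(res2$omnibus_statistic, 0)
  expect_equal(res2$omnibus_p, 1)
})

test_that("compare_years is invariant to municipality ordering and guards n", {
  p <- generate_panel(synthetic_config(seed = 99))
  tab <- index_table(p, "aging")
  shuffled <- withr::with_seed(1, tab[sample(nrow(tab)), ])
  a <- compare_years(tab); b <- compare_years(shuffled)
  expect_equal(a$omnibus_statistic, b$omnibus_statistic)
  expect_equal(a$pairwise$adjusted_p, b$pairwise$adjusted_p)

  small <- index_table(census_panel(as.data.frame(p)[p$municipality == "M01", ]),
                       "aging")
  expect_error(compare_years(small), class = "savr_insufficient_data_error")
})
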