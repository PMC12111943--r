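test_that("decade prevalence is the end-of-decade surgery-to-elderly ratio", {
  expect_equal(round(decade_prevalence(2424, 535894), 2), 0.45)
  # 2011 regional 65+ population implied by back-projecting 535,894 at 1.4%/yr
  expect_equal(round(decade_prevalence(1538, 535894 / 1.014^10), 2), 0.33)
  expect_equal(decade_prevalence(0, 1e5), 0)
  expect_equal(decade_prevalence(surgery_decade(2011, 2021, 2424), 535894),
               100 * 2424 / 535894)

  withr::with_seed(41, {
    for (i in 1:30) {
      s <- sample(0:5000, 1); p <- sample(1e4:1e6, 1)
      expect_equal(decade_prevalence(s, p), 100 * s / p, tolerance = 1e-12)
    }
  })
  expect_error(decade_prevalence(10, 0), class = "savr_domain_error")
})

test_that("projected surgeries apply the prevalence with half-up rounding", {
  expect_equal(projected_surgeries(0.45, 650506), 2927)
  expect_equal(projected_surgeries(0.45, 688335), 3098)
  expect_equal(projected_surgeries(0, 1e9), 0)

  # monotone non-decreasing in both arguments
  withr::with_seed(43, {
    for (i in 1:20) {
      prev <- runif(1, 0, 2); pop <- sample(1e4:1e6, 1)
      expect_gte(projected_surgeries(prev + 0.1, pop),
                 projected_surgeries(prev, pop))
      expect_gte(projected_surgeries(prev, pop + 5000),
                 projected_surgeries(prev, pop))
      # prevalence of the projection recovers the input within rounding
      back <- decade_prevalence(projected_surgeries(prev, pop), pop)
      expect_lt(abs(back - prev), 0.005 + 100 * 0.5 / pop)
    }
  })
})

test_that("demand summaries report decade and per-year increments", {
  ref <- surgery_decade(2011, 2021, 2424)
  d1 <- demand_summary(2927, ref)
  expect_equal(d1$decade_increase, 503)
  expect_equal(d1$per_year_exact, 50.3)
  d2 <- demand_summary(3098, ref)
  expect_equal(d2$decade_increase, 674)
  expect_equal(d2$per_year_exact, 67.4)

  expect_equal(demand_summary(2424, ref)$decade_increase, 0)
  expect_equal(demand_summary(2424, ref)$per_year_exact, 0)

  # rounding policies
  expect_equal(demand_summary(2927, ref, "ceil")$per_year_reported, 51)
  expect_equal(demand_summary(2927, ref, "nearest")$per_year_reported, 50)
  expect_equal(demand_summary(3098, ref, "ceil")$per_year_reported, 68)
  expect_equal(demand_summary(3098, ref, "nearest")$per_year_reported, 67)

  tab <- demand_table(c(decreasing = 650506, stagnation = 688335), 0.45, ref)
  expect_equal(tab$projected_surgeries, c(2927, 3098))
  expect_equal(tab$decade_increase, c(503, 674))
  expect_equal(tab$per_year_exact, c(50.3, 67.4))
})

test_that("binomial registries recover the true prevalence with small bias", {
  p_end <- 5e5
  truth <- 0.45
  ests <- withr::with_seed(47, {
    vapply(1:500, function(i) {
      s <- rbinom(1, p_end, truth / 100)
      decade_prevalence(s, p_end)
    }, numeric(1))
  })
  expect_lt(abs(mean(ests) - truth), 0.01)
})

test_that("surgery registries validate decade spans and round-trip via CSV", {
  expect_error(surgery_decade(2011, 2020, 10), class = "savr_validation_error")
  expect_error(surgery_registry(2001, 2011, -1), class = "savr_validation_error")
  expect_error(surgery_registry(2001, 2011, 2.5), class = "savr_validation_error")

  reg <- surgery_registry(c(2001, 2011), c(2011, 2021), c(1538, 2424))
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(reg, f)
  reg2 <- read_registry_csv(f)
  expect_equal(as.data.frame(reg2), as.data.frame(reg))
})

test_that("annual trends match the closed-form least-squares solution", {
  yrs <- 2001:2012
  perfect <- annual_trend(yrs, 100 + 2 * (yrs - 2001))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$r_squared, 1)

  flat <- annual_trend(yrs, rep(50, length(yrs)))
  expect_identical(flat$slope, 0)
  expect_true(is.na(flat$r_squared))

  withr::with_seed(53, {
    y <- 100 + 8 * (yrs - 2001) + rnorm(length(yrs), 0, 15)
    fit <- annual_trend(yrs, y)
    # normal-equations oracle
    xc <- yrs - mean(yrs); yc <- y - mean(y)
    slope_oracle <- sum(xc * yc) / sum(xc^2)
    r2_oracle <- sum((slope_oracle * xc)^2) / sum(yc^2)
    expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
    expect_equal(fit$r_squared, r2_oracle, tolerance = 1e-12)
  })

  expect_error(annual_trend(2001:2002, c(1, 2)),
               class = "savr_insufficient_data_error")
  expect_error(annual_trend(rep(2001, 3), c(1, 2, 3)), class = "savr_fit_error")
})
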