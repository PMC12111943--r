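test_that("census records enforce the band-partition and 75+ invariants", {
  rec <- census_record("Lisboa", 2021, 100, 20, 60, 20, 10)
  expect_s3_class(rec, "census_record")
  expect_equal(rec$pop_0_14 + rec$pop_15_64 + rec$pop_65_plus, rec$pop_total)

  expect_error(census_record("Lisboa", 2021, 101, 20, 60, 20, 10),
               class = "savr_validation_error")
  expect_error(census_record("Lisboa", 2021, 100, 20, 60, 20, 25),
               class = "savr_validation_error")
  expect_error(census_record("Lisboa", 2021, 100, -20, 100, 20, 10),
               class = "savr_validation_error")
  expect_error(census_record("Lisboa", 2021, 100.5, 20, 60.5, 20, 10),
               class = "savr_validation_error")
  # missing 75+ column is allowed
  expect_true(is.na(census_record("Lisboa", 2021, 100, 20, 60, 20)$pop_75_plus))
})

test_that("panels reject duplicate keys and flag unbalanced panels", {
  p <- tiny_panel()
  expect_true(attr(p, "complete"))
  expect_error(census_panel(rbind(p, p[1, ])), class = "savr_validation_error")

  unbal <- census_panel(p[-1, ])
  expect_false(attr(unbal, "complete"))
  expect_error(census_panel(p[-1, ], require_balanced = TRUE),
               class = "savr_validation_error")
})

test_that("census CSV parsing accepts thousands separators, rejects decimals", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "municipality,year,sex,pop_total,pop_0_14,pop_15_64,pop_65_plus,pop_75_plus",
    '"Lisboa",2021,all,"1,042,214","150,000","692,214","200,000","90,000"',
    "Mafra,2021,all,10000,2000,6000,2000,900"
  ), f)
  p <- read_census_csv(f)
  expect_equal(p$pop_total[p$municipality == "Lisboa"], 1042214)
  expect_equal(p$pop_75_plus[p$municipality == "Mafra"], 900)

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "municipality,year,sex,pop_total,pop_0_14,pop_15_64,pop_65_plus,pop_75_plus",
    'X,2021,all,"10,5",2,6,2,1'
  ), g)
  expect_error(read_census_csv(g), class = "savr_schema_error")
})

test_that("schema errors name the missing column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("municipality,year,pop_total,pop_0_14,pop_15_64", "A,2001,9,3,6"), f)
  expect_error(read_census_csv(f), "pop_65_plus",
               class = "savr_schema_error")
  expect_error(read_census_csv(withr::local_tempfile()),
               class = "savr_schema_error")
})

test_that("write/read round trip is the identity on valid panels", {
  p <- generate_panel(synthetic_config(seed = 202))
  f <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(p, f)
  p2 <- read_census_csv(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  expect_equal(attr(p2, "complete"), attr(p, "complete"))

  # empty panel -> header-only file that reads back empty
  empty <- census_panel(p[0, ])
  g <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(empty, g)
  expect_length(readLines(g), 1)
  expect_equal(nrow(read_census_csv(g)), 0)
})

test_that("sex-stratified panels keep one row per (municipality, year, sex)", {
  p <- sex_panel()
  f <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(p, f)
  p2 <- read_census_csv(f)
  expect_equal(nrow(p2), 6)
  expect_setequal(unique(p2$sex), c("all", "female", "male"))
  expect_equal(as.data.frame(p2), as.data.frame(p))
})

test_that("regional aggregation sums every band and matches a column-sum oracle", {
  p <- tiny_panel()
  one <- aggregate_region(p, "Beta", 2011, name = "Beta")
  expect_equal(as.data.frame(one),
               as.data.frame(p[p$municipality == "Beta" & p$year == 2011, ]),
               ignore_attr = TRUE)

  two <- aggregate_region(p, c("Alfa", "Beta"), 2011)
  expect_equal(two$pop_65_plus,
               sum(p$pop_65_plus[p$municipality %in% c("Alfa", "Beta") &
                                   p$year == 2011]))

  # brute-force oracle on a synthetic panel, order independence
  sp <- generate_panel(synthetic_config(seed = 77))
  sub <- as.data.frame(sp[sp$year == 2021, ])
  reg <- aggregate_region(sp, "all", 2021)
  for (col in c("pop_total", "pop_0_14", "pop_15_64", "pop_65_plus", "pop_75_plus")) {
    expect_equal(reg[[col]], sum(sub[[col]]))
  }
  shuffled <- aggregate_region(sp, rev(panel_municipalities(sp)), 2021)
  expect_equal(as.data.frame(shuffled), as.data.frame(reg))

  expect_error(aggregate_region(p, "Nowhere", 2011), class = "savr_lookup_error")
  expect_error(aggregate_region(p, "Alfa", 1991), class = "savr_lookup_error")
})

test_that("pyramid summaries partition the total and support sex splits", {
  p <- tiny_panel()
  tot <- pyramid_summary(p, 2011, bands = "total")
  expect_equal(tot$count, aggregate_region(p, "all", 2011)$pop_total)

  broad <- pyramid_summary(p, 2011, bands = "broad")
  expect_equal(sum(broad$count), tot$count)
  split4 <- pyramid_summary(p, 2011, bands = "elderly_split")
  expect_equal(sum(split4$count), tot$count)

  sx <- sex_panel()
  by_sex <- pyramid_summary(sx, 2001, bands = "broad", by_sex = TRUE)
  expect_equal(sum(by_sex$count),
               pyramid_summary(sx, 2001, bands = "total")$count)
  # the published 2001 male regional total is reproduced from its records
  male_total <- sum(by_sex$count[by_sex$sex == "male"])
  expect_equal(male_total, 1042214)

  expect_error(pyramid_summary(p, 2011, by_sex = TRUE),
               class = "savr_capability_error")
})
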