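test_that("aggregating the 2022 census reproduces the published totals", {
  demo <- census_totals(salvia_census(), 2022)
  expect_equal(demo$total, 506)
  expect_equal(demo$adult, 118)
  expect_equal(demo$adult_pct, 23.32)
  expect_equal(demo$juvenile, 365)
  expect_equal(demo$juvenile_pct, 72.13)
  expect_equal(demo$seedling, 23)
  expect_equal(demo$seedling_pct, 4.55)
  expect_error(census_totals(salvia_census(), 1990),
               class = "nichepop_lookup_error")
})

test_that("per-record stage percentages match the published parentheticals", {
  census <- salvia_census()
  pct <- stage_percentages(census[!is.na(census$adult), ])
  # published percents are reproduced within +/-0.01 everywhere
  published <- tibble::tribble(
    ~site, ~year, ~adult_pct, ~juvenile_pct, ~seedling_pct,
    "TNFP1", 2021, 0.00, 93.75, 6.25,
    "TNFP1", 2022, 20.00, 80.00, 0.00,
    "TNFP2", 2021, 30.88, 59.80, 9.31,
    "TNFP2", 2022, 37.58, 52.02, 10.40,
    "ZEFR1", 2021, 20.83, 79.17, 0.00,
    "ZEFR1", 2022, 21.43, 78.57, 0.00,
    "ZEFR2", 2022, 13.14, 85.04, 1.83,
    "TGM", 2021, 26.67, 73.33, 0.00,
    "TGM", 2022, 36.67, 63.33, 0.00
  )
  joined <- dplyr::inner_join(pct, published, by = c("site", "year"),
                              suffix = c("", "_pub"))
  expect_equal(nrow(joined), 9)
  tol <- 0.01 + 1e-9 # published cells carry their own rounding
  expect_true(all(abs(joined$adult_pct - joined$adult_pct_pub) <= tol))
  expect_true(all(abs(joined$juvenile_pct - joined$juvenile_pct_pub) <= tol))
  expect_true(all(abs(joined$seedling_pct - joined$seedling_pct_pub) <= tol))

  # degenerate cases
  one <- tibble::tibble(site = "s", year = 2022L, total = 10L, adult = 10L,
                        juvenile = 0L, seedling = 0L)
  expect_equal(stage_percentages(one)$adult_pct, 100)
  zero <- tibble::tibble(site = "s", year = 2022L, total = 0L, adult = 0L,
                         juvenile = 0L, seedling = 0L)
  expect_error(stage_percentages(zero), class = "nichepop_validation_error")
})

test_that("aggregation is associative: sites-then-stages equals stages-then-sites", {
  census <- sim_census(n_sites = 6, years = 2020:2022, initial_total = 150,
                       decline_rate = 0.2, seed = 17)
  demo <- census_totals(census, 2022)
  by_site <- census[census$year == 2022, ]
  expect_equal(demo$total, sum(by_site$adult) + sum(by_site$juvenile) +
                 sum(by_site$seedling))
})

test_that("decline flags compare the two most recent surveys per site", {
  flags <- decline_flags(salvia_census())
  per <- flags$per_site
  expect_false(per$declined[per$site == "TGM"])     # 15 -> 30
  expect_true(per$declined[per$site == "TNFP2"])    # 204 -> 173
  expect_true(flags$overall)
  # the site first surveyed in the latest year carries no trend
  expect_false("ZEFR2" %in% per$site)

  const <- tibble::tibble(site = "s", year = 2021:2022, total = c(5L, 5L),
                          adult = c(1L, 1L), juvenile = c(4L, 4L),
                          seedling = c(0L, 0L))
  expect_false(decline_flags(const)$per_site$declined)

  single <- const[1, ]
  expect_error(decline_flags(single), class = "nichepop_validation_error")
})

test_that("censored historical bounds follow the configured policy", {
  # site with only a <200 bound then a small count
  rec <- tibble::tibble(
    site = "s", year = c(2019L, 2022L), total = c(NA_integer_, 30L),
    adult = NA_integer_, juvenile = NA_integer_, seedling = NA_integer_,
    total_upper_bound = c(200L, NA_integer_)
  )
  expect_true(decline_flags(rec, "pessimistic")$per_site$declined)
  expect_false(decline_flags(rec, "optimistic")$per_site$declined)
})
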