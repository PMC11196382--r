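test_that("plot surveys round-trip through CSV with validation intact", {
  path <- write_survey_csv(toy_survey())
  tbl <- read_plot_survey(path)
  expect_equal(as.data.frame(tbl), as.data.frame(toy_survey()))

  # schema remapping resolves nonstandard headers
  odd <- toy_survey()
  names(odd)[names(odd) == "cover_pct"] <- "coverage"
  path2 <- write_survey_csv(odd)
  tbl2 <- read_plot_survey(path2, schema = c(cover_pct = "coverage"))
  expect_equal(tbl2$cover_pct, toy_survey()$cover_pct)
})

test_that("malformed surveys raise exactly one typed error each", {
  missing_col <- toy_survey()[, -5]
  expect_error(read_plot_survey(write_survey_csv(missing_col)),
               class = "nichepop_schema_error")

  bad_cover <- toy_survey()
  bad_cover$cover_pct[2] <- 120
  expect_error(read_plot_survey(write_survey_csv(bad_cover)),
               class = "nichepop_validation_error")

  negative <- toy_survey()
  negative$count[1] <- -2
  expect_error(read_plot_survey(write_survey_csv(negative)),
               class = "nichepop_validation_error")

  dup <- dplyr::bind_rows(toy_survey(), toy_survey()[1, ])
  err <- expect_error(read_plot_survey(write_survey_csv(dup)),
                      class = "nichepop_validation_error")
  expect_match(conditionMessage(err), "duplicate")
})

test_that("census parsing handles counts, dashes, and censored bounds", {
  census <- salvia_census()
  y2022 <- census[census$year == 2022, ]
  expect_equal(nrow(y2022), 5)
  expect_true(all(y2022$adult + y2022$juvenile + y2022$seedling == y2022$total))

  # censored 2019 cells become bounds, not counts
  b <- census[census$year == 2019, ]
  expect_true(all(is.na(b$total)))
  expect_equal(b$total_upper_bound, c(200L, 200L))

  # stage-sum violations are reported with site and year
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,year,total,adult,juvenile,seedling",
               "X,2022,10,4,5,2"), path)
  err <- expect_error(read_census(path), class = "nichepop_validation_error")
  expect_match(conditionMessage(err), "X/2022")

  # empty file with header -> empty table
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("site,year,total,adult,juvenile,seedling", path2)
  expect_equal(nrow(read_census(path2)), 0)
})

test_that("write_table is byte-stable and renders fixed decimals", {
  tbl <- tibble::tibble(name = c("a", "b"), value = c(0.125, 2.0), n = c(1L, 2L))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(tbl, p1)
  write_table(tbl, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  lines <- readLines(p1)
  expect_equal(lines[2], "a\t0.13\t1") # half-up at the rendering boundary

  md <- withr::local_tempfile(fileext = ".md")
  write_table(tbl, md, format = "markdown")
  expect_match(readLines(md)[1], "^\\| name \\| value \\| n \\|$")
})

test_that("overlap matrices render as lower-triangular tables", {
  m <- overlap_matrix(salvia_iv_matrix())
  path <- withr::local_tempfile(fileext = ".md")
  write_table(m, path, format = "markdown")
  lines <- readLines(path)
  expect_length(lines, 15) # header + separator + 13 species rows
  expect_match(lines[3], "— \\|\\s*\\|") # diagonal dash, empty upper triangle

  # degenerate single-species matrix: a single dash diagonal cell
  one <- structure(matrix(1, 1, 1, dimnames = list("A", "A")),
                   class = c("overlap_matrix", "matrix"))
  path1 <- withr::local_tempfile(fileext = ".tsv")
  write_table(one, path1, format = "tsv")
  expect_equal(readLines(path1)[2], "1\t—")
})
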