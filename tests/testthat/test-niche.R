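test_that("breadth indices reproduce the worked reference rows", {
  sd_row <- c(10.00, 14.76, 3.42, 8.75)
  expect_equal(levins_breadth(sd_row), 3.36, tolerance = 0.005)
  expect_equal(shannon_breadth(sd_row), 0.84, tolerance = 0.005)
  expect_equal(shannon_breadth(c(16.66, 1.67, 29.51, 25.07)), 1.07,
               tolerance = 0.005)

  # forced cases
  expect_equal(levins_breadth(rep(5, 4)), 4)
  expect_equal(levins_breadth(c(7, 0, 0, 0)), 1)
  expect_equal(shannon_breadth(rep(5, 4), convention = "normalized"), log(4))
  expect_error(levins_breadth(c(0, 0)), class = "nichepop_validation_error")
  expect_error(shannon_breadth(c(0, 0)), class = "nichepop_validation_error")
})

test_that("uniform occupancy maximises normalised Levins breadth (grid oracle)", {
  # brute-force search over the 3-plot simplex at 0.01 resolution
  grid <- expand.grid(p1 = seq(0.01, 0.98, by = 0.01),
                      p2 = seq(0.01, 0.98, by = 0.01))
  grid$p3 <- 1 - grid$p1 - grid$p2
  grid <- grid[grid$p3 > 0, ]
  vals <- apply(as.matrix(grid), 1, levins_breadth)
  expect_lte(max(vals), 3)
  best <- as.numeric(grid[which.max(vals), ])
  expect_equal(best, rep(1 / 3, 3), tolerance = 0.02)
})

test_that("pianka overlap matches reference pairs and algebraic limits", {
  sd_row <- c(10.00, 14.76, 3.42, 8.75)
  hc_row <- c(5.67, 6.30, 1.59, 1.01)
  expect_equal(pianka_overlap(sd_row, hc_row), 0.94, tolerance = 0.005)
  expect_equal(pianka_overlap(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pianka_overlap(c(1, 0), c(0, 1)), 0)
  expect_error(pianka_overlap(c(1, 2), c(1, 2, 3)), class = "nichepop_param_error")
})

test_that("overlap is invariant to positive rescaling of either species", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(2:6, 1)
      a <- runif(n) * rbinom(n, 1, 0.7)
      b <- runif(n) * rbinom(n, 1, 0.7)
      if (all(a == 0) || all(b == 0)) next
      k <- runif(1, 0.01, 50)
      expect_equal(pianka_overlap(a * k, b), pianka_overlap(a, b),
                   tolerance = 1e-12)
      expect_equal(pianka_overlap(a, b * k), pianka_overlap(b, a),
                   tolerance = 1e-12)
    }
  })
})

test_that("overlap matrices are symmetric with unit diagonal and support-driven zeros", {
  m <- overlap_matrix(salvia_iv_matrix())
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(1, 13))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))
  # zero exactly where plot supports are disjoint
  ivm <- salvia_iv_matrix()
  for (i in 1:12) for (j in (i + 1):13) {
    disjoint <- sum(ivm[i, ] * ivm[j, ]) == 0
    expect_equal(m[i, j] == 0, disjoint)
  }
  # proportional rows overlap completely
  prop <- rbind(a = c(1, 2, 0), b = c(2, 4, 0))
  expect_equal(overlap_matrix(prop)["a", "b"], 1)
})

test_that("the overlap census over the published matrix gives 78/43/13", {
  cen <- overlap_census(salvia_overlap(), threshold = 0.5)
  expect_equal(cen$n_pairs, 78)
  expect_equal(cen$n_at_or_above, 43)
  expect_equal(cen$n_zero, 13)
  expect_equal(cen$pct_at_or_above, 100 * 43 / 78, tolerance = 1e-9)

  # the inclusive threshold matters: strictly greater would drop the
  # published 0.50 cell
  pairs <- overlap_pairs(salvia_overlap())
  expect_equal(sum(pairs$overlap > 0.5), 42)

  all_ones <- structure(matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3])),
                        class = c("overlap_matrix", "matrix"))
  cen3 <- overlap_census(all_ones, threshold = 0.5)
  expect_equal(cen3$n_at_or_above, 3)
  expect_equal(cen3$n_zero, 0)
  expect_equal(overlap_census(all_ones, threshold = 0)$n_at_or_above, 3)
  expect_error(overlap_census(all_ones, threshold = 2),
               class = "nichepop_param_error")
})

test_that("breadth conventions split as documented", {
  tbl_classic <- niche_breadth(salvia_iv_matrix())
  tbl_norm <- niche_breadth(salvia_iv_matrix(), convention = "normalized")
  # Levins is normalisation-invariant; Shannon differs between modes
  expect_equal(tbl_classic$b_levins, tbl_norm$b_levins)
  expect_false(any(abs(tbl_classic$b_shannon - tbl_norm$b_shannon) < 1e-6))
  # normalised Levins bounded by plot count, with 1 at specialists
  expect_true(all(tbl_classic$b_levins >= 1 & tbl_classic$b_levins <= 4))
})
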