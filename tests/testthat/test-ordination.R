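make_xy <- function(n = 20, p = 3, q = 5, noise = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    B <- matrix(rnorm(p * q), p, q)
    Y <- X %*% B + noise * matrix(rnorm(n * q), n, q)
    colnames(Y) <- paste0("y", seq_len(q))
    list(X = X, Y = Y)
  })
}

test_that("standardisation centres, scales, and rejects constant columns", {
  d <- make_xy()$Y
  z <- standardize_columns(d)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(d)))
  expect_equal(standardize_columns(z), z, tolerance = 1e-12)
  bad <- cbind(d, const = 1)
  err <- expect_error(standardize_columns(bad), class = "nichepop_validation_error")
  expect_match(conditionMessage(err), "const")
  expect_equal(max(abs(colMeans(standardize_columns(d, "center")))), 0,
               tolerance = 1e-12)
})

test_that("a noiseless linear response is fully constrained", {
  d <- make_xy(noise = 0)
  fit <- rda_fit(d$Y, d$X)
  expect_equal(fit$total_constrained_pct, 100, tolerance = 1e-9)
})

test_that("variance is conserved and eigenvalues behave", {
  d <- make_xy(n = 24, p = 4, q = 6, seed = 8)
  fit <- rda_fit(d$Y, d$X)
  expect_equal(sum(fit$eigenvalues) + sum(fit$residual_eigenvalues),
               fit$total_variance, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(diff(fit$axis_explained_pct) <= 1e-12))
  expect_lte(fit$total_constrained_pct, 100 + 1e-9)
  # adding an explanatory variable never decreases constrained variance
  fit3 <- rda_fit(d$Y, d$X[, 1:3])
  fit2 <- rda_fit(d$Y, d$X[, 1:2])
  expect_gte(fit3$constrained_variance, fit2$constrained_variance - 1e-12)
})

test_that("constrained axes reduce to PCA under a full orthonormal basis", {
  # 5 samples x 4 traits; X spans the whole centred sample space, so the
  # fitted values equal Y and the axes must match a direct spectral
  # decomposition of Y's covariance
  withr::with_seed(31, {
    Y <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("y", 1:4)))
  })
  X <- qr.Q(qr(stats::contr.helmert(5))) # 5 x 4 orthonormal, columns sum to 0
  colnames(X) <- paste0("b", 1:4)
  fit <- rda_fit(Y, X, standardize = "center")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  oracle <- eigen(crossprod(Yc) / 4, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$total_constrained_pct, 100, tolerance = 1e-9)
  expect_equal(fit$eigenvalues, oracle[seq_along(fit$eigenvalues)],
               tolerance = 1e-9)
})

test_that("eigenvalues agree with an independent constrained-ordination fit", {
  skip_if_not_installed("vegan")
  d <- make_xy(n = 30, p = 4, q = 7, seed = 12)
  fit <- rda_fit(d$Y, d$X)
  ref <- vegan::rda(
    standardize_columns(d$Y) ~ .,
    data = as.data.frame(standardize_columns(d$X))
  )
  expect_equal(unname(fit$eigenvalues),
               unname(ref$CCA$eig[seq_along(fit$eigenvalues)]),
               tolerance = 1e-9)
  expect_equal(fit$total_variance, unname(ref$tot.chi), tolerance = 1e-9)
})

test_that("rank-deficient explanatory matrices name the collinear column", {
  d <- make_xy()
  X <- cbind(d$X, dup = d$X[, 1] * 2 + d$X[, 2])
  # z-scoring rescales but keeps the linear dependence
  err <- expect_error(rda_fit(d$Y, X), class = "nichepop_validation_error")
  expect_match(conditionMessage(err), "collinear")
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- make_xy(seed = 5)
  fit <- rda_fit(d$Y, d$X)
  td <- tidy(fit)
  expect_named(td, c("axis", "eigenvalue", "explained_pct", "cumulative_pct"))
  expect_equal(td$cumulative_pct[nrow(td)], fit$total_constrained_pct)
  gl <- glance(fit)
  expect_equal(gl$n, 20)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("forward selection orders variables, floors p, and is reproducible", {
  d <- make_xy(n = 25, p = 3, q = 4, noise = 0.3, seed = 4)
  sel <- forward_select(d$Y, d$X, n_perm = 99, seed = 2)
  expect_equal(nrow(sel), 3)
  expect_equal(sort(sel$variable), paste0("x", 1:3))
  # contributions over the full selection partition the explainable variance
  expect_equal(sum(sel$contribution_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(sel$added_variance) <= 1e-12))
  # strong signal bottoms out at the permutation floor 1/(n_perm + 1)
  expect_equal(sel$p_value[1], 1 / 100)
  sel2 <- forward_select(d$Y, d$X, n_perm = 99, seed = 2)
  expect_identical(sel, sel2)
  # away from the permutation floor the p-value depends on the stream
  weak <- make_xy(n = 25, p = 3, q = 4, noise = 6, seed = 4)
  w1 <- forward_select(weak$Y, weak$X, n_perm = 99, seed = 2)
  w2 <- forward_select(weak$Y, weak$X, n_perm = 99, seed = 3)
  expect_false(identical(w1$p_value, w2$p_value))
  expect_error(forward_select(d$Y, d$X, n_perm = 50),
               class = "nichepop_param_error")
})

test_that("a dominant organic-matter effect is recovered from simulated soils", {
  soil <- sim_soil_traits(n_samples = 60, om_effect = 1, ph_effect = -0.5,
                          seed = 7)
  traits <- as.matrix(soil[trait_vocabulary()])
  svars <- as.matrix(soil[soil_vocabulary()])
  sel <- forward_select(traits, svars, n_perm = 99, seed = 7)
  expect_equal(sel$variable[1], "OM")
  expect_equal(which.max(sel$contribution_pct), 1L)
  fit <- rda_fit(traits, svars)
  expect_gt(fit$axis_explained_pct[1], fit$axis_explained_pct[2])
  expect_equal(rownames(fit$biplot_scores)[which.max(abs(fit$biplot_scores[, 1]))],
               "OM")
})
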