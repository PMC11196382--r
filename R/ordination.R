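# Redundancy analysis from first principles.  The response matrix Y
# (growth/flowering traits) is regressed on the explanatory matrix X
# (soil variables) by multivariate least squares; the constrained axes
# are the principal axes of the fitted values, and their eigenvalues
# partition the fitted variance.  Forward selection ranks explanatory
# variables by added explained variance, with pseudo-F statistics and
# permutation p-values obtained by permuting reduced-model residuals.

#' Column standardisation
#'
#' Centres columns (mode `"center"`) or centres and scales them to unit
#' variance (mode `"zscore"`).  Constant columns cannot be z-scored and
#' raise an error naming the offending variables.
#'
#' @param m Numeric matrix or data frame of numeric columns.
#' @param mode `"zscore"` (default) or `"center"`.
#' @return Numeric matrix with column means 0 (and unit variance under
#'   `"zscore"`).
#' @export
standardize_columns <- function(m, mode = c("zscore", "center")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop_param("standardisation needs at least 2 rows")
  if (anyNA(m)) stop_validation("matrix contains missing values")
  ctr <- scale(m, center = TRUE, scale = FALSE)
  attr(ctr, "scaled:center") <- NULL
  if (mode == "center") {
    return(ctr[, , drop = FALSE])
  }
  s <- apply(m, 2, sd)
  const <- which(s < .Machine$double.eps^0.5)
  if (length(const)) {
    nm <- colnames(m)[const] %||% as.character(const)
    stop_validation(paste0(
      "constant column(s) cannot be z-scored: ", paste(nm, collapse = ", ")
    ))
  }
  sweep(ctr, 2, s, "/")
}

# fitted-value projection of (centred) Y on (centred) X, via QR
project_fitted <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_validation(paste0(
      "explanatory matrix is rank-deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  qr.fitted(qx, Y)
}

# sum of column variances (total inertia after centring)
total_inertia <- function(M) sum(colSums(M^2)) / (nrow(M) - 1)

#' Fit a redundancy analysis
#'
#' @param Y Response matrix or data frame (samples x traits).
#' @param X Explanatory matrix or data frame (samples x variables); the
#'   number of samples must exceed the number of explanatory variables.
#' @param standardize Standardisation applied to both matrices before
#'   fitting: `"zscore"` (default; appropriate when columns mix units)
#'   or `"center"`.
#' @return An object of class `rda_fit` with elements
#'   `eigenvalues` (constrained axis eigenvalues, non-increasing),
#'   `axis_explained_pct` (percent of total response variance per
#'   constrained axis), `total_constrained_pct`, `total_variance`,
#'   `residual_eigenvalues`, `site_scores` (sample coordinates on the
#'   constrained axes, from fitted values), `response_scores` (trait
#'   loadings), `biplot_scores` (correlations of explanatory variables
#'   with the site scores), and `n`.
#' @seealso [forward_select()], [tidy.rda_fit()], [autoplot.rda_fit()]
#' @examples
#' soil <- sim_soil_traits(n_samples = 30, seed = 7)
#' fit <- rda_fit(soil[trait_vocabulary()], soil[c("OM", "pH")])
#' tidy(fit)
#' @export
rda_fit <- function(Y, X, standardize = c("zscore", "center")) {
  standardize <- match.arg(standardize)
  Y <- standardize_columns(Y, standardize)
  X <- standardize_columns(X, standardize)
  if (nrow(Y) != nrow(X)) stop_param("`Y` and `X` must have the same rows")
  n <- nrow(Y)
  if (n <= ncol(X)) {
    stop_param("the number of samples must exceed the number of explanatory variables")
  }
  Yhat <- project_fitted(Y, X)
  Yres <- Y - Yhat
  tot <- total_inertia(Y)
  eig_all <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  keep <- eig_all$values > max(eig_all$values[1], 0) * 1e-12
  keep[1] <- eig_all$values[1] > 0
  lambda <- eig_all$values[keep]
  V <- eig_all$vectors[, keep, drop = FALSE]
  rownames(V) <- colnames(Y)
  colnames(V) <- paste0("RDA", seq_len(ncol(V)))
  site <- Yhat %*% V
  rownames(site) <- rownames(Y)
  biplot <- cor(X, site)
  res_eig <- eigen(crossprod(Yres) / (n - 1), symmetric = TRUE,
                   only.values = TRUE)$values
  res_eig <- res_eig[res_eig > max(res_eig[1], 0) * 1e-12]
  structure(
    list(
      eigenvalues = lambda,
      axis_explained_pct = 100 * lambda / tot,
      total_constrained_pct = 100 * sum(lambda) / tot,
      total_variance = tot,
      constrained_variance = sum(lambda),
      residual_eigenvalues = res_eig,
      site_scores = site,
      response_scores = V,
      biplot_scores = biplot,
      n = n,
      standardize = standardize
    ),
    class = "rda_fit"
  )
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis (", x$n, " samples, ",
      length(x$eigenvalues), " constrained axes)\n", sep = "")
  cat(sprintf("Constrained variance: %.2f%% of total\n", x$total_constrained_pct))
  axes <- utils::head(x$axis_explained_pct, 5)
  cat(paste(sprintf("  %s: %.2f%%", names(axes) %||%
                      paste0("RDA", seq_along(axes)), axes), collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy an RDA fit: one row per constrained axis
#'
#' @param x An `rda_fit` object.
#' @param ... Unused.
#' @return Tibble `axis`, `eigenvalue`, `explained_pct`,
#'   `cumulative_pct`.
#' @export
tidy.rda_fit <- function(x, ...) {
  tibble(
    axis = paste0("RDA", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    explained_pct = x$axis_explained_pct,
    cumulative_pct = cumsum(x$axis_explained_pct)
  )
}

#' One-row summary of an RDA fit
#'
#' @param x An `rda_fit` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_axes`, `total_variance`,
#'   `constrained_variance`, `total_constrained_pct`.
#' @export
glance.rda_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_axes = length(x$eigenvalues),
    total_variance = x$total_variance,
    constrained_variance = x$constrained_variance,
    total_constrained_pct = x$total_constrained_pct
  )
}

#' Biplot of an RDA fit
#'
#' Samples as points on the first two constrained axes, explanatory
#' variables as labelled arrows (correlation biplot scores, scaled to
#' the score range).
#'
#' @param object An `rda_fit` object with at least two constrained axes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rda_fit <- function(object, ...) {
  if (length(object$eigenvalues) < 2) {
    stop_param("a biplot needs at least two constrained axes")
  }
  sites <- as_tibble(object$site_scores[, 1:2, drop = FALSE],
                     .name_repair = "minimal")
  names(sites) <- c("RDA1", "RDA2")
  arrows <- as_tibble(object$biplot_scores[, 1:2, drop = FALSE],
                      .name_repair = "minimal")
  names(arrows) <- c("RDA1", "RDA2")
  arrows$variable <- rownames(object$biplot_scores)
  r <- max(abs(unlist(sites))) * 0.9
  arrows <- mutate(arrows, RDA1 = .data$RDA1 * r, RDA2 = .data$RDA2 * r)
  labs <- sprintf("RDA%d (%.1f%%)", 1:2, object$axis_explained_pct[1:2])
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$RDA1, y = .data$RDA2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = 0, y = 0, xend = .data$RDA1, yend = .data$RDA2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "firebrick"
    ) +
    ggplot2::geom_text(
      data = arrows,
      ggplot2::aes(label = .data$variable), colour = "firebrick",
      vjust = -0.6, size = 3
    ) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' Forward selection of explanatory variables
#'
#' Greedy forward selection for redundancy analysis: at each step the
#' candidate variable adding the most explained (fitted) variance joins
#' the model; ties break lexicographically by variable name.  For the
#' selected variable the pseudo-F statistic is
#' `(added variance / 1) / (residual variance / (n - k - 1))`, with `k`
#' the number of variables in the model including the new one, and its
#' p-value comes from a permutation test that permutes the residuals of
#' the reduced model (the model without the candidate), the standard
#' conditional scheme for constrained ordination.
#'
#' @param Y,X,standardize As in [rda_fit()]; selection runs until all
#'   columns of `X` are in the model (or `steps` variables), in
#'   selection order.
#' @param n_perm Number of permutations (at least 99; default 999).  The
#'   smallest attainable p-value is `1 / (n_perm + 1)`.
#' @param seed Integer seed making the permutation stream reproducible.
#' @param steps Maximum number of selection steps (default: all
#'   variables).
#' @return A tibble with one row per selection step: `step`, `variable`,
#'   `added_variance`, `contribution_pct` (percent of the all-variable
#'   constrained variance, so the column sums to 100), `cum_explained_pct`
#'   (percent of total response variance explained so far), `pseudo_f`,
#'   `p_value`.
#' @examples
#' soil <- sim_soil_traits(n_samples = 30, seed = 7)
#' forward_select(soil[trait_vocabulary()], soil[c("OM", "pH", "K")],
#'                n_perm = 99, seed = 1)
#' @export
forward_select <- function(Y, X, n_perm = 999, seed = 1,
                           standardize = c("zscore", "center"),
                           steps = Inf) {
  standardize <- match.arg(standardize)
  if (n_perm < 99) stop_param("`n_perm` must be at least 99")
  X <- standardize_columns(X, standardize)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!ncol(X)) stop_param("`X` must contain at least one variable")
  Y <- standardize_columns(Y, standardize)
  n <- nrow(Y)
  if (n <= ncol(X) + 1) {
    stop_param("forward selection needs more samples than explanatory variables + 1")
  }
  tot <- total_inertia(Y)
  explainable <- total_inertia(project_fitted(Y, X))
  constrained <- function(cols, Ymat) {
    if (!length(cols)) 0 else
      total_inertia(project_fitted(Ymat, X[, cols, drop = FALSE]))
  }
  withr::with_seed(seed, {
    n_steps <- min(ncol(X), steps)
    selected <- character()
    out <- vector("list", n_steps)
    base_var <- 0
    for (step in seq_len(n_steps)) {
      candidates <- setdiff(colnames(X), selected)
      added <- vapply(candidates,
                      function(v) constrained(c(selected, v), Y) - base_var,
                      numeric(1))
      ord <- order(-added, candidates)
      pick <- candidates[ord[1]]
      add_obs <- added[[pick]]
      k <- length(selected) + 1
      new_var <- base_var + add_obs
      f_obs <- (add_obs / 1) / ((tot - new_var) / (n - k - 1))
      # permutation of reduced-model residuals
      if (length(selected)) {
        fit_red <- project_fitted(Y, X[, selected, drop = FALSE])
      } else {
        fit_red <- matrix(0, n, ncol(Y))
      }
      res_red <- Y - fit_red
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        Yb <- fit_red + res_red[sample.int(n), , drop = FALSE]
        vb <- constrained(c(selected, pick), Yb)
        ab <- vb - constrained(selected, Yb)
        fb <- (ab / 1) / ((total_inertia(Yb) - vb) / (n - k - 1))
        if (fb >= f_obs) exceed <- exceed + 1L
      }
      out[[step]] <- tibble(
        step = step, variable = pick, added_variance = add_obs,
        contribution_pct = 100 * add_obs / explainable,
        cum_explained_pct = 100 * new_var / tot,
        pseudo_f = f_obs,
        p_value = (1 + exceed) / (n_perm + 1)
      )
      selected <- c(selected, pick)
      base_var <- new_var
    }
    dplyr::bind_rows(out)
  })
}
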