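# Niche breadth and overlap over plots-as-resource-states.  A species'
# per-plot importance values play the role of its resource-use vector:
# Levins breadth 1/sum(p^2), Shannon breadth -sum(p ln p), and the
# Pianka overlap index between species pairs.

#' Levins niche breadth
#'
#' `1 / sum(p^2)` with the proportions normalised within the species
#' (`p_k = iv_k / sum(iv)`), so the breadth ranges from 1 (single-plot
#' specialist) to the number of plots (uniform occupancy).
#'
#' @param iv_row Numeric vector of per-plot importance values (or any
#'   non-negative resource-use measure) with at least one positive entry.
#' @return Levins breadth (dimensionless).
#' @examples
#' levins_breadth(c(10.00, 14.76, 3.42, 8.75)) # 3.36 to 2 dp
#' levins_breadth(c(7, 0, 0, 0)) # 1, a single-plot specialist
#' @export
levins_breadth <- function(iv_row) {
  check_iv_row(iv_row)
  p <- iv_row / sum(iv_row)
  1 / sum(p^2)
}

#' Shannon niche breadth
#'
#' `-sum(p ln p)` with `0 ln 0` taken as 0.  Under the `"iv-fraction"`
#' convention (the default, which reproduces how breadth columns of
#' classical importance-value tables are computed) `p_k = iv_k / 100`,
#' i.e. the percent IVs are read directly as fractions without
#' renormalising within the species.  Under `"normalized"`,
#' `p_k = iv_k / sum(iv)`, the information-theoretic form bounded by
#' `ln`(number of plots).
#'
#' @inheritParams levins_breadth
#' @param convention `"iv-fraction"` or `"normalized"` (see Details).
#' @return Shannon breadth (dimensionless, natural log).
#' @examples
#' shannon_breadth(c(10.00, 14.76, 3.42, 8.75)) # 0.84 to 2 dp
#' shannon_breadth(rep(5, 4), convention = "normalized") # log(4)
#' @export
shannon_breadth <- function(iv_row, convention = c("iv-fraction", "normalized")) {
  convention <- match.arg(convention)
  check_iv_row(iv_row)
  p <- if (convention == "iv-fraction") iv_row / 100 else iv_row / sum(iv_row)
  p <- p[p > 0]
  -sum(p * log(p))
}

check_iv_row <- function(iv_row) {
  if (!is.numeric(iv_row) || !length(iv_row)) {
    stop_param("`iv_row` must be a non-empty numeric vector")
  }
  if (any(iv_row < 0)) stop_param("importance values must be non-negative")
  if (all(iv_row == 0)) {
    stop_validation("niche breadth is undefined for an all-zero row")
  }
  invisible(iv_row)
}

#' Niche breadth table for every species
#'
#' Computes Levins and Shannon breadth per species from a long
#' importance tibble ([importance_values()]) or a species x plot matrix.
#' The default `"classic"` convention pairs the per-species-normalised
#' Levins form with the IV-fraction Shannon form — the pairing under
#' which the breadth columns of classical quadrat-survey tables are
#' computed.  `"normalized"` applies within-species normalisation to
#' both.
#'
#' @param iv Long importance tibble with `species`, `plot_id`, `iv`
#'   columns, or a numeric species x plot matrix with rownames.
#' @param convention `"classic"` (default) or `"normalized"`.
#' @return Tibble with `species`, `b_levins`, `b_shannon`, `convention`,
#'   in the input's species order.
#' @seealso [levins_breadth()], [shannon_breadth()], [overlap_matrix()]
#' @export
niche_breadth <- function(iv, convention = c("classic", "normalized")) {
  convention <- match.arg(convention)
  m <- as_iv_matrix(iv)
  shannon_mode <- if (convention == "classic") "iv-fraction" else "normalized"
  tibble(
    species = rownames(m),
    b_levins = apply(m, 1, levins_breadth),
    b_shannon = apply(m, 1, shannon_breadth, convention = shannon_mode),
    convention = convention
  )
}

as_iv_matrix <- function(iv) {
  if (is.matrix(iv)) {
    if (is.null(rownames(iv))) rownames(iv) <- sprintf("sp%02d", seq_len(nrow(iv)))
    return(iv)
  }
  if (is.data.frame(iv)) {
    if (!all(c("species", "plot_id", "iv") %in% names(iv))) {
      stop_param("`iv` must have columns species, plot_id, iv (or be a matrix)")
    }
    # preserve first-appearance order rather than pivot_wider's grouping
    sp <- unique(iv$species)
    m <- iv_matrix(iv)
    return(m[sp, , drop = FALSE])
  }
  stop_param("`iv` must be a data frame or a numeric matrix")
}

#' Pianka niche overlap between two species
#'
#' `sum(p_i p_j) / sqrt(sum(p_i^2) sum(p_j^2))` over plots.  The index
#' is invariant to rescaling either vector by a positive constant
#' (the normalisations cancel), so raw importance values can be passed
#' directly.  It equals 1 iff the vectors are proportional and 0 iff
#' their supports are disjoint.
#'
#' @param iv_i,iv_j Numeric per-plot vectors of equal length, each with
#'   at least one positive entry.
#' @return Overlap in \[0, 1\].
#' @examples
#' pianka_overlap(c(10.00, 14.76, 3.42, 8.75), c(5.67, 6.30, 1.59, 1.01))
#' pianka_overlap(c(1, 0), c(0, 1)) # disjoint supports: 0
#' @export
pianka_overlap <- function(iv_i, iv_j) {
  if (length(iv_i) != length(iv_j)) {
    stop_param("`iv_i` and `iv_j` must have the same length")
  }
  check_iv_row(iv_i)
  check_iv_row(iv_j)
  sum(iv_i * iv_j) / sqrt(sum(iv_i^2) * sum(iv_j^2))
}

#' Pairwise Pianka overlap matrix
#'
#' @param iv Long importance tibble or species x plot matrix (at least
#'   two species).
#' @return A symmetric species x species matrix with unit diagonal, of
#'   class `overlap_matrix`.  Write it with [write_table()] for the
#'   conventional lower-triangular layout, or tidy it with
#'   [overlap_pairs()].
#' @export
overlap_matrix <- function(iv) {
  m <- as_iv_matrix(iv)
  if (nrow(m) < 2) stop_param("an overlap matrix needs at least two species")
  n <- nrow(m)
  o <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      o[i, j] <- o[j, i] <- pianka_overlap(m[i, ], m[j, ])
    }
  }
  dimnames(o) <- list(rownames(m), rownames(m))
  class(o) <- c("overlap_matrix", class(o))
  o
}

#' Tidy the strict lower triangle of an overlap matrix
#'
#' @param m An `overlap_matrix` (or any symmetric numeric matrix).
#' @return Tibble with `species_i`, `species_j`, `overlap`, one row per
#'   unordered species pair, in row-major lower-triangle order.
#' @export
overlap_pairs <- function(m) {
  n <- nrow(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble(
    species_i = rownames(m)[idx[, "row"]],
    species_j = colnames(m)[idx[, "col"]],
    overlap = m[idx]
  )
}

#' Census of an overlap matrix
#'
#' Counts, over the `n(n-1)/2` unordered pairs, how many overlap values
#' reach `threshold` (inclusive `>=`, so a printed 0.50 cell counts at
#' threshold 0.50) and how many are zero.  On recomputed matrices zeros
#' are detected numerically (`|o| < zero_tol`), not by rounding to 0.00.
#'
#' @param m An `overlap_matrix` or a pairs tibble from [overlap_pairs()].
#' @param threshold Census threshold in \[0, 1\] (default 0.50).
#' @param zero_tol Numerical zero tolerance (default 1e-12).
#' @return One-row tibble: `n_pairs`, `n_at_or_above`, `pct_at_or_above`,
#'   `n_zero`, `pct_zero`, `threshold`.
#' @examples
#' overlap_census(salvia_overlap()) # 78 pairs, 43 at/above 0.50, 13 zeros
#' @export
overlap_census <- function(m, threshold = 0.5, zero_tol = 1e-12) {
  if (threshold < 0 || threshold > 1) stop_param("`threshold` must be in [0, 1]")
  o <- if (is.data.frame(m)) m$overlap else overlap_pairs(m)$overlap
  tibble(
    n_pairs = length(o),
    n_at_or_above = sum(o >= threshold),
    pct_at_or_above = 100 * sum(o >= threshold) / length(o),
    n_zero = sum(abs(o) < zero_tol),
    pct_zero = 100 * sum(abs(o) < zero_tol) / length(o),
    threshold = threshold
  )
}
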