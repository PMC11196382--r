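# Bundled reference tables for the Salvia daiguii community of
# Zhangjiajie (Hunan, China), transcribed from the published field
# survey of that community: the importance values of the 13 dominant
# herbs (IV > 1%) across the four 5 m x 10 m quadrats, the 2019-2022
# stage-structured census of the five known sites, and the published
# 13 x 13 niche-overlap matrix.  These ship as plain CSV under
# inst/extdata/ and are the worked-example inputs throughout the
# package.

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "nichepop", mustWork = FALSE)
  if (!nzchar(path)) stop_config(paste0("bundled fixture not found: ", file))
  path
}

#' Importance values of the 13 dominant herbs in the *Salvia daiguii* community
#'
#' Species x quadrat importance values (percent) for the 13 species with
#' IV above 1% in the four-quadrat survey of the community (two quadrats
#' each at the ZEFR and TNFP populations), transcribed from the
#' published survey.  Species are ordered by decreasing mean IV.
#'
#' @param long If `TRUE`, return the tidy long layout of
#'   [importance_values()] (columns `species`, `plot_id`, `iv`);
#'   otherwise the wide species x plot tibble as stored.
#' @return A tibble.
#' @seealso [niche_breadth()], [overlap_matrix()], [iv_summary()]
#' @export
salvia_importance <- function(long = FALSE) {
  wide <- readr::read_csv(fixture_path("salvia_importance_13x4.csv"),
                          show_col_types = FALSE, progress = FALSE)
  if (!long) return(wide)
  tidyr::pivot_longer(wide, -"species", names_to = "plot_id", values_to = "iv")
}

#' Importance-value matrix of the *S. daiguii* community fixture
#'
#' @return 13 x 4 numeric matrix (species x quadrat) of percent IVs.
#' @export
salvia_iv_matrix <- function() {
  wide <- salvia_importance()
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$species
  m
}

#' 2019-2022 census of the five *S. daiguii* sites
#'
#' Stage-structured counts (total, adult, juvenile, seedling) for the
#' five known sites.  The 2019 figures are censored bounds (`<200`) and
#' parse into `total_upper_bound`; stage breakdowns were not recorded
#' that year.
#'
#' @return A census tibble (see [read_census()]).
#' @export
salvia_census <- function() {
  read_census(fixture_path("salvia_census_2019_2022.csv"))
}

#' Published niche-overlap matrix of the *S. daiguii* community
#'
#' The 13 x 13 Pianka overlap matrix as printed in the published survey
#' (lower triangle, 2 decimals), with species numbered as in
#' [salvia_importance()].  Kept separately from the recomputable matrix
#' because a few printed cells reflect the survey's unrounded working
#' values and differ slightly from what the rounded printed IVs give.
#'
#' @return An `overlap_matrix` with the fixture's species names.
#' @export
salvia_overlap <- function() {
  pairs <- readr::read_csv(fixture_path("salvia_overlap_published.csv"),
                           show_col_types = FALSE, progress = FALSE)
  species <- salvia_importance()$species
  n <- length(species)
  m <- diag(n)
  m[cbind(pairs$species_i, pairs$species_j)] <- pairs$overlap
  m[cbind(pairs$species_j, pairs$species_i)] <- pairs$overlap
  dimnames(m) <- list(species, species)
  class(m) <- c("overlap_matrix", class(m))
  m
}
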