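# Seeded simulators for the three data kinds the analyses consume.  Each
# generator uses one explicit RNG stream scoped to the call (the caller's
# .Random.seed is untouched) so identical seeds give identical tables.

#' Simulate a quadrat-survey herb community
#'
#' Draws a plot x species survey with site-restricted occupancy:
#' each species occurs in a plot with probability `occupancy`
#' (conditioned on occurring somewhere), counts are rounded-lognormal
#' (heavy-tailed abundances, as observed in herbaceous communities where
#' importance values span two orders of magnitude), heights are
#' truncated-normal in cm, and covers are Beta-distributed fractions
#' scaled to percent.
#'
#' @param n_species,n_plots Community size; both must be at least 2.
#'   Defaults emulate a 62-species, 4-quadrat herb survey.
#' @param occupancy Per-species probability of occurring in any given
#'   plot, in (0, 1].
#' @param abundance_logmean,abundance_logsd Lognormal parameters for
#'   counts (rounded, floored at 1 individual where present).
#' @param height_mean,height_sd Normal parameters for species mean height
#'   (cm), truncated to be positive.
#' @param cover_concentration Beta(1, `cover_concentration`) shape for
#'   cover fractions; larger values give sparser cover.
#' @param seed Integer seed for the generator's private RNG stream.
#' @return A validated plot-survey tibble (see [read_plot_survey()]).
#' @examples
#' survey <- sim_community(n_species = 10, n_plots = 4, seed = 1)
#' importance_values(survey)
#' @export
sim_community <- function(n_species = 62, n_plots = 4, occupancy = 0.4,
                          abundance_logmean = 1.5, abundance_logsd = 1,
                          height_mean = 25, height_sd = 10,
                          cover_concentration = 8, seed = 1) {
  if (n_species < 2) stop_param("`n_species` must be at least 2")
  if (n_plots < 2) stop_param("`n_plots` must be at least 2")
  if (occupancy <= 0 || occupancy > 1) stop_param("`occupancy` must be in (0, 1]")
  if (cover_concentration <= 0) stop_param("`cover_concentration` must be positive")
  withr::with_seed(seed, {
    species <- sprintf("sp%03d", seq_len(n_species))
    plots <- sprintf("plot%02d", seq_len(n_plots))
    pres <- matrix(
      rbinom(n_species * n_plots, 1L, occupancy) == 1L,
      nrow = n_species
    )
    none <- which(rowSums(pres) == 0)
    for (i in none) pres[i, sample.int(n_plots, 1L)] <- TRUE
    obs <- purrr::map_dfr(seq_len(n_plots), function(k) {
      idx <- which(pres[, k])
      m <- length(idx)
      tibble(
        plot_id = plots[k],
        species = species[idx],
        count = pmax(1L, as.integer(round(rlnorm(m, abundance_logmean, abundance_logsd)))),
        mean_height_cm = pmax(0.5, rnorm(m, height_mean, height_sd)),
        cover_pct = pmin(100, pmax(0.01, 100 * rbeta(m, 1, cover_concentration)))
      )
    })
    validate_plot_survey(obs)
  })
}

#' Simulate a declining stage-structured census series
#'
#' Totals follow binomial thinning between consecutive surveys: each
#' individual survives an interval with probability `1 - decline_rate`,
#' so totals decline in expectation by `decline_rate` per interval.
#' Stage counts (adult, juvenile, seedling) are multinomial given the
#' total, so stage sums always equal totals exactly.
#'
#' @param n_sites Number of sites, each started at `initial_total`.
#' @param years Increasing vector of survey years (at least one).
#' @param initial_total First-survey total per site.
#' @param decline_rate Expected proportional loss per survey interval,
#'   in \[0, 1).
#' @param stage_probs Length-3 simplex of (adult, juvenile, seedling)
#'   probabilities.  The default (0.23, 0.72, 0.05) mirrors the
#'   juvenile-dominated, recruitment-limited structure typical of relict
#'   cliff-herb populations.
#' @param seed Integer seed.
#' @return A census tibble in the layout of [read_census()].
#' @examples
#' sim_census(n_sites = 2, years = 2021:2022, seed = 3)
#' @export
sim_census <- function(n_sites = 5, years = c(2021L, 2022L),
                       initial_total = 200, decline_rate = 0.15,
                       stage_probs = c(0.23, 0.72, 0.05), seed = 1) {
  if (!length(years)) stop_param("`years` must contain at least one survey year")
  if (is.unsorted(years, strictly = TRUE)) stop_param("`years` must be strictly increasing")
  if (decline_rate < 0 || decline_rate >= 1) stop_param("`decline_rate` must be in [0, 1)")
  if (length(stage_probs) != 3 || any(stage_probs < 0) ||
      abs(sum(stage_probs) - 1) > 1e-8) {
    stop_param("`stage_probs` must be a 3-element simplex summing to 1")
  }
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_sites), function(s) {
      totals <- integer(length(years))
      totals[1] <- as.integer(initial_total)
      for (k in seq_along(years)[-1]) {
        totals[k] <- rbinom(1L, totals[k - 1], 1 - decline_rate)
      }
      stages <- vapply(
        totals,
        function(tot) as.integer(rmultinom(1L, tot, stage_probs)),
        integer(3)
      )
      tibble(
        site = sprintf("site%02d", s), year = as.integer(years),
        total = totals, adult = stages[1, ], juvenile = stages[2, ],
        seedling = stages[3, ], total_upper_bound = NA_integer_
      )
    })
    validate_census(out)
    out
  })
}

#' Simulate a paired soil-chemistry and plant-trait table
#'
#' Emulates the causal structure in which organic matter has a dominant
#' positive effect and pH a (typically negative) effect on growth and
#' flowering, with the remaining soil variables as weak nuisance
#' predictors.  Organic matter spans a wide range (default 44-118 g/kg,
#' the span observed between nutrient-poor cliff soils and enriched
#' garden substrate); pH sits in a narrow, slightly alkaline band.  Each
#' trait is `om_effect * scale(OM) + ph_effect * scale(pH) + nuisance +
#' noise` on its standardised scale.
#'
#' @param n_samples Number of samples; must exceed the number of soil
#'   variables plus one or the downstream ordination is rank-deficient.
#' @param om_effect Standardised effect of organic matter on every trait.
#' @param ph_effect Standardised effect of pH (negative by default).
#' @param nuisance_sd Standard deviation of the random small coefficients
#'   given to the other soil variables.
#' @param noise_sd Residual standard deviation; must be positive.
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `site`, the 13 soil variables and
#'   11 trait variables, carrying `soil_vars`/`trait_vars` attributes as
#'   [read_soil_traits()] would attach.
#' @examples
#' soil <- sim_soil_traits(n_samples = 30, seed = 7)
#' @export
sim_soil_traits <- function(n_samples = 60, om_effect = 1, ph_effect = -0.5,
                            nuisance_sd = 0.1, noise_sd = 0.5, seed = 1) {
  if (noise_sd <= 0) stop_param("`noise_sd` must be positive")
  soil_vars <- soil_vocabulary()
  trait_vars <- trait_vocabulary()
  if (n_samples < length(soil_vars) + 2) {
    stop_param(paste0(
      "`n_samples` must be at least ", length(soil_vars) + 2,
      " (number of soil variables + 2) for a full-rank ordination"
    ))
  }
  withr::with_seed(seed, {
    soil <- tibble(
      pH = rnorm(n_samples, 7.9, 0.15),
      EC = rlnorm(n_samples, log(0.15), 0.4),
      OM = runif(n_samples, 44, 118),
      N = rnorm(n_samples, 4.8, 1.2),
      P = rlnorm(n_samples, log(1.0), 0.8),
      K = rnorm(n_samples, 20, 8),
      AN = rnorm(n_samples, 290, 55),
      AP = rlnorm(n_samples, log(60), 1),
      AK = rnorm(n_samples, 125, 25),
      CEC = rnorm(n_samples, 13, 3),
      B = rnorm(n_samples, 1.85, 0.1),
      S = rnorm(n_samples, 33, 12),
      SM = pmin(95, pmax(5, rnorm(n_samples, 68, 12)))
    )
    zscore <- function(x) (x - mean(x)) / sd(x)
    nuis_vars <- setdiff(soil_vars, c("OM", "pH"))
    nuis_z <- vapply(soil[nuis_vars], zscore, numeric(n_samples))
    signal <- om_effect * zscore(soil$OM) + ph_effect * zscore(soil$pH)
    # trait means/scales loosely follow field-observed magnitudes
    trait_mean <- c(PHE = 20, CD = 19, NT = 5, NL = 30, NI = 5, NB = 4,
                    NV = 9, NF = 6, NBF = 3, NBFPI = 70, NFP = 550)
    trait_scale <- c(PHE = 6, CD = 7, NT = 4, NL = 15, NI = 3, NB = 2,
                     NV = 1.2, NF = 1.2, NBF = 0.7, NBFPI = 60, NFP = 450)
    traits <- purrr::map(trait_vars, function(tr) {
      coefs <- rnorm(length(nuis_vars), 0, nuisance_sd)
      z <- signal + as.numeric(nuis_z %*% coefs) + rnorm(n_samples, 0, noise_sd)
      trait_mean[[tr]] + trait_scale[[tr]] * z
    })
    names(traits) <- trait_vars
    out <- dplyr::bind_cols(
      tibble(
        sample_id = sprintf("s%03d", seq_len(n_samples)),
        site = sprintf("site%02d", rep_len(1:3, n_samples))
      ),
      soil, as_tibble(traits)
    )
    attr(out, "soil_vars") <- soil_vars
    attr(out, "trait_vars") <- trait_vars
    out
  })
}
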