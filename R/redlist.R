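# Rule engine for IUCN Red List (v3.1) criteria C and D and a screen
# for China's Plant Species with Extremely Small Populations (PSESP).
# Criteria A, B and E need range, trend-rate or quantitative-analysis
# inputs that census data alone do not supply and are deliberately not
# encoded.

category_order <- c("CR" = 3, "EN" = 2, "VU" = 1, "NT/not listed under these criteria" = 0)

new_assessment <- function(category, criteria_code, rationale, inputs) {
  structure(
    list(category = category, criteria_code = criteria_code,
         rationale = rationale, inputs = inputs),
    class = "redlist_assessment"
  )
}

#' Assess IUCN criterion C (small population size and decline)
#'
#' Applies the mature-individual thresholds of criterion C — fewer than
#' 250 (CR), 2,500 (EN), or 10,000 (VU) mature individuals — and, for
#' subcriterion C2, requires an observed continuing decline together
#' with at least one qualifying condition: a(i) no subpopulation larger
#' than a per-category threshold (50/250/1,000 mature individuals), or
#' b, extreme fluctuation in the number of mature individuals.
#' Extreme fluctuation is accepted as an asserted input, not computed.
#'
#' @param mature_individuals Count of mature (reproductive) individuals.
#' @param continuing_decline Logical: has a continuing decline been
#'   observed, projected, or inferred?
#' @param extreme_fluctuation Logical: are mature numbers subject to
#'   extreme fluctuation (condition b)?
#' @param largest_subpop_mature Optional count of mature individuals in
#'   the largest subpopulation, enabling condition a(i)/a(ii).
#' @return A `redlist_assessment`: `category` (`"CR"`, `"EN"`, `"VU"` or
#'   `"NT/not listed under these criteria"`), `criteria_code` (e.g.
#'   `"C2b"`, empty when not listed), and a `rationale` listing every
#'   threshold comparison that fired.
#' @examples
#' assess_criterion_c(118, continuing_decline = TRUE,
#'                    extreme_fluctuation = TRUE) # CR C2b
#' @export
assess_criterion_c <- function(mature_individuals,
                               continuing_decline = FALSE,
                               extreme_fluctuation = FALSE,
                               largest_subpop_mature = NULL) {
  if (is.null(mature_individuals) || is.na(mature_individuals) ||
      mature_individuals < 0) {
    stop_param("`mature_individuals` must be a non-negative count")
  }
  if (!is.null(largest_subpop_mature) &&
      largest_subpop_mature > mature_individuals) {
    stop_param("`largest_subpop_mature` cannot exceed `mature_individuals`")
  }
  thresholds <- c(CR = 250, EN = 2500, VU = 10000)
  subpop_thresholds <- c(CR = 50, EN = 250, VU = 1000)
  inputs <- list(
    mature_individuals = mature_individuals,
    continuing_decline = continuing_decline,
    extreme_fluctuation = extreme_fluctuation,
    largest_subpop_mature = largest_subpop_mature
  )
  cat_hit <- names(thresholds)[mature_individuals < thresholds]
  if (!length(cat_hit)) {
    return(new_assessment(
      "NT/not listed under these criteria", "",
      sprintf("mature individuals (%d) >= 10000: criterion C does not apply",
              mature_individuals),
      inputs
    ))
  }
  category <- cat_hit[1]
  rationale <- sprintf(
    "mature individuals (%d) < %d: qualifies for %s under criterion C",
    mature_individuals, thresholds[[category]], category
  )
  if (!isTRUE(continuing_decline)) {
    return(new_assessment(
      "NT/not listed under these criteria", "",
      c(rationale,
        "no continuing decline: subcriterion C2 not met, criterion C does not apply"),
      inputs
    ))
  }
  rationale <- c(rationale, "continuing decline observed: subcriterion 2 attached")
  letters <- character()
  if (!is.null(largest_subpop_mature) &&
      largest_subpop_mature <= subpop_thresholds[[category]]) {
    letters <- c(letters, "a(i)")
    rationale <- c(rationale, sprintf(
      "largest subpopulation (%d mature) <= %d: condition a(i) met",
      largest_subpop_mature, subpop_thresholds[[category]]
    ))
  }
  if (isTRUE(extreme_fluctuation)) {
    letters <- c(letters, "b")
    rationale <- c(rationale,
                   "extreme fluctuation in mature individuals: condition b met")
  }
  if (!length(letters)) {
    return(new_assessment(
      "NT/not listed under these criteria", "",
      c(rationale,
        "no qualifying condition (a(i), a(ii) or b): C2 not met"),
      inputs
    ))
  }
  new_assessment(category, paste0("C2", paste(letters, collapse = "")),
                 rationale, inputs)
}

#' Assess IUCN criterion D (very small population)
#'
#' Fewer than 50 mature individuals is CR D, fewer than 250 is EN D, and
#' fewer than 1,000 is VU D1.
#'
#' @param mature_individuals Count of mature individuals.
#' @return A `redlist_assessment`.
#' @examples
#' assess_criterion_d(118) # EN D
#' @export
assess_criterion_d <- function(mature_individuals) {
  if (is.null(mature_individuals) || is.na(mature_individuals) ||
      mature_individuals < 0) {
    stop_param("`mature_individuals` must be a non-negative count")
  }
  inputs <- list(mature_individuals = mature_individuals)
  if (mature_individuals < 50) {
    new_assessment("CR", "D",
                   sprintf("mature individuals (%d) < 50: CR under criterion D",
                           mature_individuals), inputs)
  } else if (mature_individuals < 250) {
    new_assessment("EN", "D",
                   sprintf("mature individuals (%d) < 250: EN under criterion D",
                           mature_individuals), inputs)
  } else if (mature_individuals < 1000) {
    new_assessment("VU", "D1",
                   sprintf("mature individuals (%d) < 1000: VU under criterion D1",
                           mature_individuals), inputs)
  } else {
    new_assessment("NT/not listed under these criteria", "",
                   sprintf("mature individuals (%d) >= 1000: criterion D does not apply",
                           mature_individuals), inputs)
  }
}

#' Screen for Plant Species with Extremely Small Populations (PSESP)
#'
#' The PSESP designation targets species with very few mature
#' individuals restricted to very few populations.  The listing criteria
#' are descriptive policy, so the cutoffs here are explicit
#' configuration: by default fewer than `5000` mature individuals and at
#' most `5` populations.
#'
#' @param mature_individuals Count of mature individuals.
#' @param n_populations Number of known populations.
#' @param max_mature Mature-count cutoff (strict `<`).
#' @param max_populations Population-count cutoff (inclusive `<=`).
#' @return A list with logical `psesp` and a `rationale` character
#'   vector listing both comparisons.
#' @examples
#' psesp_screen(118, 3) # TRUE
#' @export
psesp_screen <- function(mature_individuals, n_populations,
                         max_mature = 5000, max_populations = 5) {
  if (is.null(max_mature) || is.null(max_populations) ||
      is.na(max_mature) || is.na(max_populations)) {
    stop_config("PSESP cutoffs `max_mature` and `max_populations` must be set")
  }
  small <- mature_individuals < max_mature
  restricted <- n_populations <= max_populations && max_populations > 0
  list(
    psesp = small && restricted,
    rationale = c(
      sprintf("mature individuals %d %s cutoff %s", mature_individuals,
              if (small) "<" else ">=", format(max_mature)),
      sprintf("populations %d %s cutoff %s", n_populations,
              if (restricted) "<=" else ">", format(max_populations))
    )
  )
}

#' @export
print.redlist_assessment <- function(x, ...) {
  code <- if (nzchar(x$criteria_code)) paste0(" ", x$criteria_code) else ""
  cat("IUCN assessment: ", x$category, code, "\n", sep = "")
  cat(paste0("  - ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.redlist_assessment <- function(x, ...) {
  tibble(
    category = x$category,
    criteria_code = x$criteria_code,
    mature_individuals = x$inputs$mature_individuals,
    n_rules_fired = length(x$rationale)
  )
}
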