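# Aggregation of stage-structured censuses and decline detection.

#' Aggregate a census year across sites
#'
#' Sums the stage counts of every site surveyed in `year` and attaches
#' stage percentages (half-up, 2 decimals).
#'
#' @param records Census tibble as returned by [read_census()] or
#'   [sim_census()].
#' @param year Survey year to aggregate.
#' @return One-row tibble: `year`, `n_sites`, `total`, `adult`,
#'   `adult_pct`, `juvenile`, `juvenile_pct`, `seedling`, `seedling_pct`.
#' @examples
#' census_totals(salvia_census(), 2022) # total 506, 23.32/72.13/4.55 %
#' @export
census_totals <- function(records, year) {
  rows <- records[!is.na(records$year) & records$year == year, ]
  if (!nrow(rows)) {
    stop_lookup(paste0("no census records for year ", year))
  }
  total <- sum(rows$total, na.rm = TRUE)
  if (total <= 0) stop_validation("aggregate total is zero")
  stage <- function(x) sum(x, na.rm = TRUE)
  tibble(
    year = as.integer(year),
    n_sites = length(unique(rows$site)),
    total = total,
    adult = stage(rows$adult),
    adult_pct = round_half_up(100 * stage(rows$adult) / total),
    juvenile = stage(rows$juvenile),
    juvenile_pct = round_half_up(100 * stage(rows$juvenile) / total),
    seedling = stage(rows$seedling),
    seedling_pct = round_half_up(100 * stage(rows$seedling) / total)
  )
}

#' Per-record life-stage percentages
#'
#' Percent of each record's total in the adult, juvenile, and seedling
#' stages, half-up to 2 decimals; records with missing stage data get
#' `NA` percents.
#'
#' @param records Census tibble (any number of rows; totals must be
#'   positive where stages are present).
#' @return Tibble `site`, `year`, `total`, `adult_pct`, `juvenile_pct`,
#'   `seedling_pct`.
#' @export
stage_percentages <- function(records) {
  known <- !is.na(records$total)
  if (any(records$total[known] == 0 & (!is.na(records$adult[known])))) {
    stop_validation("stage percentages are undefined for a zero total")
  }
  pct <- function(x) round_half_up(100 * x / records$total)
  tibble(
    site = records$site, year = records$year, total = records$total,
    adult_pct = pct(records$adult),
    juvenile_pct = pct(records$juvenile),
    seedling_pct = pct(records$seedling)
  )
}

#' Flag continuing population decline
#'
#' Compares, per site, the totals of the two most recent surveys.  A
#' historical record that only bounds the count (for example `<200`) is
#' censored: under the default `"pessimistic"` policy the bound itself
#' is used as the earlier total (a later count below the bound is read
#' as decline — the natural reading when a population falls from "under
#' 200" to a handful of plants); under `"optimistic"` a comparison
#' against a censored value is never flagged, because the true earlier
#' count could have been arbitrarily small.
#'
#' The overall flag compares aggregate totals between the two most
#' recent survey years over the sites surveyed in both (sites first
#' recorded in the latest year have no trend information and are
#' excluded).
#'
#' @param records Census tibble with at least two survey years for at
#'   least one site.
#' @param censored_policy `"pessimistic"` (default) or `"optimistic"`.
#' @return An object of class `decline_flags`: a list with `per_site`
#'   (tibble `site`, `year_prev`, `year_latest`, `total_prev`,
#'   `total_latest`, `prev_censored`, `declined`) and logical `overall`.
#' @examples
#' flags <- decline_flags(salvia_census())
#' flags$overall
#' @export
decline_flags <- function(records, censored_policy = c("pessimistic", "optimistic")) {
  censored_policy <- match.arg(censored_policy)
  if (!"total_upper_bound" %in% names(records)) {
    records$total_upper_bound <- NA_integer_
  }
  multi <- records |>
    group_by(.data$site) |>
    filter(dplyr::n() >= 2) |>
    ungroup()
  if (!nrow(multi)) {
    stop_validation("decline needs at least two survey years for at least one site")
  }
  per_site <- multi |>
    group_by(.data$site) |>
    arrange(.data$year, .by_group = TRUE) |>
    summarise(
      year_prev = .data$year[dplyr::n() - 1],
      year_latest = .data$year[dplyr::n()],
      total_prev = dplyr::coalesce(
        .data$total[dplyr::n() - 1],
        .data$total_upper_bound[dplyr::n() - 1]
      ),
      total_latest = .data$total[dplyr::n()],
      prev_censored = is.na(.data$total[dplyr::n() - 1]) &
        !is.na(.data$total_upper_bound[dplyr::n() - 1])
    ) |>
    ungroup() |>
    mutate(
      declined = dplyr::case_when(
        .data$prev_censored & censored_policy == "optimistic" ~ FALSE,
        TRUE ~ .data$total_latest < .data$total_prev
      )
    )
  years <- sort(unique(records$year))
  overall <- NA
  if (length(years) >= 2) {
    latest <- years[length(years)]
    prev <- years[length(years) - 1]
    both <- intersect(
      records$site[records$year == prev],
      records$site[records$year == latest]
    )
    a <- records[records$year == prev & records$site %in% both, ]
    b <- records[records$year == latest & records$site %in% both, ]
    tot <- function(x) {
      t <- dplyr::coalesce(x$total, if (censored_policy == "pessimistic")
        x$total_upper_bound else NA_integer_)
      if (anyNA(t)) NA_integer_ else sum(t)
    }
    overall <- isTRUE(tot(b) < tot(a))
  }
  structure(list(per_site = per_site, overall = overall),
            class = "decline_flags")
}

#' @export
print.decline_flags <- function(x, ...) {
  cat("Population decline flags\n")
  print(x$per_site)
  cat("Overall decline (comparable sites, two most recent years): ",
      x$overall, "\n", sep = "")
  invisible(x)
}
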