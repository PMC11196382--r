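# Species importance values from quadrat surveys.  Within each plot the
# importance value of a species is the mean of its relative abundance,
# relative height, and relative cover, each expressed as a percent of
# the plot total, so the IVs of all species in a plot sum to 100.

#' Relative abundance, height, and cover within one plot
#'
#' For every species observed in `plot_id`, computes the three relative
#' components as percents of the plot totals: RA from counts, RH from
#' per-species mean heights (unweighted by count), RC from percent
#' cover.  Each component vector sums to 100.
#'
#' @param survey A validated plot-survey tibble.
#' @param plot_id Plot identifier present in the survey.
#' @return Tibble with columns `species`, `ra`, `rh`, `rc`.
#' @examples
#' survey <- tibble::tibble(
#'   plot_id = "p1", species = c("A", "B"),
#'   count = c(3, 1), mean_height_cm = c(10, 30), cover_pct = c(30, 10)
#' )
#' relative_components(survey, "p1") # RA 75/25, RH 25/75, RC 75/25
#' @export
relative_components <- function(survey, plot_id) {
  survey <- validate_plot_survey(survey)
  rows <- survey[survey$plot_id == plot_id, ]
  if (!nrow(rows)) {
    stop_lookup(paste0("no observations for plot '", plot_id, "'"))
  }
  totals <- c(sum(rows$count), sum(rows$mean_height_cm), sum(rows$cover_pct))
  if (any(totals <= 0)) {
    stop_validation(paste0(
      "plot '", plot_id, "' is degenerate: counts, heights and covers ",
      "must each have a positive total"
    ))
  }
  tibble(
    species = rows$species,
    ra = 100 * rows$count / totals[1],
    rh = 100 * rows$mean_height_cm / totals[2],
    rc = 100 * rows$cover_pct / totals[3]
  )
}

#' Importance values for every species and plot
#'
#' IV = (RA + RH + RC) / 3 per species per plot.  The result covers the
#' full species x plot grid: species absent from a plot carry IV 0 (and
#' zero components), and each plot's IVs sum to 100.
#'
#' @param survey A validated plot-survey tibble.
#' @return A long tibble with columns `species`, `plot_id`, `ra`, `rh`,
#'   `rc`, `iv`, completed over all species x plot combinations.
#'   Species are ordered by decreasing mean IV (the conventional table
#'   order), plots by first appearance.
#' @seealso [iv_matrix()], [iv_summary()], [niche_breadth()]
#' @export
importance_values <- function(survey) {
  survey <- validate_plot_survey(survey)
  plots <- unique(survey$plot_id)
  long <- purrr::map_dfr(plots, function(p) {
    mutate(relative_components(survey, p), plot_id = p, .after = "species")
  })
  long <- mutate(long, iv = (.data$ra + .data$rh + .data$rc) / 3)
  long <- tidyr::complete(
    long,
    species = unique(survey$species),
    plot_id = plots,
    fill = list(ra = 0, rh = 0, rc = 0, iv = 0)
  )
  long$plot_id <- factor(long$plot_id, levels = plots)
  ord <- long |>
    group_by(.data$species) |>
    summarise(mean_iv = mean(.data$iv)) |>
    arrange(dplyr::desc(.data$mean_iv), .data$species)
  long$species <- factor(long$species, levels = ord$species)
  out <- arrange(long, .data$species, .data$plot_id)
  out$species <- as.character(out$species)
  out$plot_id <- as.character(out$plot_id)
  out
}

#' Importance-value matrix
#'
#' Pivots the long table of [importance_values()] (or any tibble with
#' `species`, `plot_id` and a value column) into a species x plot
#' numeric matrix.
#'
#' @param iv_tbl Long importance tibble.
#' @param value Name of the value column (default `"iv"`).
#' @return Numeric matrix, species as rownames and plots as colnames.
#' @export
iv_matrix <- function(iv_tbl, value = "iv") {
  wide <- tidyr::pivot_wider(
    iv_tbl[c("species", "plot_id", value)],
    names_from = "plot_id", values_from = all_of(value)
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$species
  storage.mode(m) <- "double"
  m
}

#' Cross-plot importance summaries (mean and standard error)
#'
#' Mean IV per species over all plots, with absent plots counted as 0,
#' and its standard error.  Published community tables conventionally
#' use the population-standard-deviation form
#' `se = sqrt(sum((x - mean)^2) / n) / sqrt(n)`; set
#' `se = "sample"` for the n-1 denominator instead.
#'
#' @param iv_tbl Long importance tibble from [importance_values()].
#' @param species Optional species name(s) to restrict to; errors when a
#'   requested species is absent.
#' @param se Standard-error convention, `"population"` (default) or
#'   `"sample"`.
#' @return Tibble with `species`, `mean_iv`, `se_iv`, `n_plots`.
#' @examples
#' # a species with plot IVs 10.00, 14.76, 3.42, 8.75 summarises to
#' # mean 9.23, SE 2.02 under the population convention
#' @export
iv_summary <- function(iv_tbl, species = NULL, se = c("population", "sample")) {
  se <- match.arg(se)
  if (!is.null(species)) {
    missing <- setdiff(species, iv_tbl$species)
    if (length(missing)) {
      stop_lookup(paste0(
        "species not present in the importance table: ",
        paste(missing, collapse = ", ")
      ))
    }
    iv_tbl <- iv_tbl[iv_tbl$species %in% species, ]
  }
  se_fun <- if (se == "population") {
    function(x) sqrt(sum((x - mean(x))^2) / length(x)) / sqrt(length(x))
  } else {
    function(x) sd(x) / sqrt(length(x))
  }
  iv_tbl |>
    group_by(species = .data$species) |>
    summarise(
      mean_iv = mean(.data$iv),
      se_iv = se_fun(.data$iv),
      n_plots = dplyr::n()
    ) |>
    arrange(dplyr::desc(.data$mean_iv), .data$species)
}
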