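# ggplot2 displays for the main result types.

#' Heatmap of a niche-overlap matrix
#'
#' @param object An `overlap_matrix`.
#' @param ... Unused.
#' @return A ggplot object (lower triangle, species in matrix order).
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  pairs <- overlap_pairs(object)
  sp <- rownames(object)
  pairs <- mutate(
    pairs,
    species_i = factor(.data$species_i, levels = sp),
    species_j = factor(.data$species_j, levels = sp)
  )
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$species_j, y = .data$species_i,
                                      fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = fmt_num(.data$overlap)), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pianka\noverlap") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked life-stage structure per site and year
#'
#' @param records Census tibble with stage counts.
#' @return A ggplot object: one bar per site x year, filled by stage.
#' @export
plot_stage_structure <- function(records) {
  long <- records |>
    filter(!is.na(.data$adult)) |>
    tidyr::pivot_longer(c("adult", "juvenile", "seedling"),
                        names_to = "stage", values_to = "count") |>
    mutate(stage = factor(.data$stage, levels = c("seedling", "juvenile", "adult")))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$year), y = .data$count,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_wrap(~site) +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = "survey year", y = "stage share (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
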