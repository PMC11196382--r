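# Small in-code fixtures shared across test files.

toy_survey <- function() {
  tibble::tibble(
    plot_id = c("p1", "p1", "p2", "p2", "p2"),
    species = c("A", "B", "A", "B", "C"),
    count = c(3, 1, 2, 2, 4),
    mean_height_cm = c(10, 30, 12, 20, 8),
    cover_pct = c(30, 10, 15, 15, 40)
  )
}

write_survey_csv <- function(tbl, path = withr::local_tempfile(fileext = ".csv",
                                                               .local_envir = parent.frame())) {
  readr::write_csv(tbl, path)
  path
}

# per-species Table-layout breadth/overlap reference values, frozen from
# the bundled importance fixture
published_levins <- c(3.36, 3.05, 2.99, 1.99, 1.92, 1.92, 1.63, 2.82,
                      1.65, 1.80, 1.79, 1.97, 2.63)
published_shannon <- c(0.84, 1.03, 1.07, 0.71, 0.50, 0.47, 0.43, 0.45,
                       0.34, 0.31, 0.26, 0.25, 0.17)
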