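# End-to-end orchestration: ingest (or simulate) -> importance values ->
# niche breadth/overlap -> demography -> red-list assessment ->
# ordination, rendering publication-shaped tables, a JSON summary and a
# log of every convention switch actually used.

#' Run the full assessment pipeline
#'
#' `config` is a YAML file path or an equivalent nested list with the
#' blocks:
#' \describe{
#'   \item{inputs}{`survey`, `census`, `soil_traits` file paths.  Any of
#'     the three may instead come from a `simulate` block.}
#'   \item{simulate}{`community`, `census`, `soil` parameter lists
#'     passed to [sim_community()], [sim_census()], [sim_soil_traits()].}
#'   \item{conventions}{`breadth` (`"classic"`/`"normalized"`), `se`
#'     (`"population"`/`"sample"`), `overlap_threshold` (default 0.5),
#'     `censored_policy`, `standardize`, `min_iv_pct` (display filter
#'     for the importance table, never applied before niche metrics).}
#'   \item{assessment}{`continuing_decline` (default: taken from the
#'     census decline flags), `extreme_fluctuation`, `n_populations`,
#'     `mature_individuals` (default: latest-year adult total).}
#'   \item{ordination}{`n_perm` (default 999).}
#'   \item{seed}{Integer driving every simulation and permutation.}
#'   \item{out_dir}{Output directory for tables, `summary.json`,
#'     `pipeline.log`.}
#' }
#'
#' @param config Path to a YAML config or a list.
#' @param out_dir Overrides the config's output directory.
#' @return Invisibly, a list with the computed tables (`importance`,
#'   `breadth`, `overlap`, `overlap_census`, `demography`, `decline`,
#'   `assessment`, `selection`, `ordination`) plus `summary` (what was
#'   written to JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("`config` must be a YAML path or a list")
  conv <- config$conventions %||% list()
  breadth_conv <- conv$breadth %||% "classic"
  se_conv <- conv$se %||% "population"
  threshold <- conv$overlap_threshold %||% 0.5
  censored <- conv$censored_policy %||% "pessimistic"
  standardize <- conv$standardize %||% "zscore"
  min_iv <- conv$min_iv_pct %||% 0
  seed <- config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir
  log_lines <- c(
    sprintf("seed: %d", as.integer(seed)),
    sprintf("breadth convention: %s", breadth_conv),
    sprintf("SE convention: %s", se_conv),
    sprintf("overlap threshold (inclusive): %.2f", threshold),
    sprintf("censored-census policy: %s", censored),
    sprintf("ordination standardisation: %s", standardize)
  )

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "nichepop_pipeline_error", parent = e)
    })
  }

  # --- ingest / simulate -----------------------------------------------
  survey <- stage("ingest-survey", {
    if (!is.null(config$inputs$survey)) read_plot_survey(config$inputs$survey)
    else if (!is.null(config$simulate$community)) {
      do.call(sim_community, utils::modifyList(list(seed = seed),
                                               config$simulate$community))
    } else NULL
  })
  census <- stage("ingest-census", {
    if (!is.null(config$inputs$census)) read_census(config$inputs$census)
    else if (!is.null(config$simulate$census)) {
      do.call(sim_census, utils::modifyList(list(seed = seed),
                                            config$simulate$census))
    } else {
      stop_config("config provides neither a census input nor a census simulation block")
    }
  })
  soil <- stage("ingest-soil", {
    if (!is.null(config$inputs$soil_traits)) read_soil_traits(config$inputs$soil_traits)
    else if (!is.null(config$simulate$soil)) {
      do.call(sim_soil_traits, utils::modifyList(list(seed = seed),
                                                 config$simulate$soil))
    } else NULL
  })

  # --- importance + niche ----------------------------------------------
  iv_long <- if (!is.null(survey)) stage("importance", importance_values(survey))
  breadth <- overlap <- ocensus <- NULL
  if (!is.null(iv_long)) {
    breadth <- stage("niche", niche_breadth(iv_long, convention = breadth_conv))
    overlap <- stage("niche", overlap_matrix(iv_long))
    ocensus <- stage("niche", overlap_census(overlap, threshold = threshold))
  }

  # --- demography + assessment -----------------------------------------
  latest_year <- max(census$year, na.rm = TRUE)
  demo <- stage("demography", census_totals(census, latest_year))
  decline <- stage("demography", tryCatch(
    decline_flags(census, censored_policy = censored),
    nichepop_validation_error = function(e) NULL
  ))
  assess_cfg <- config$assessment %||% list()
  mature <- assess_cfg$mature_individuals %||% demo$adult
  decl <- assess_cfg$continuing_decline %||%
    (if (!is.null(decline)) isTRUE(decline$overall) else FALSE)
  fluct <- assess_cfg$extreme_fluctuation %||% FALSE
  npop <- assess_cfg$n_populations %||% length(unique(census$site))
  assessment <- stage("assess", assess_criterion_c(
    mature, continuing_decline = decl, extreme_fluctuation = fluct
  ))
  psesp <- stage("assess", psesp_screen(mature, npop))

  # --- ordination -------------------------------------------------------
  fit <- selection <- NULL
  if (!is.null(soil)) {
    traits <- intersect(trait_vocabulary(), names(soil))
    svars <- intersect(soil_vocabulary(), names(soil))
    fit <- stage("ordination", rda_fit(soil[traits], soil[svars],
                                       standardize = standardize))
    selection <- stage("ordination", forward_select(
      soil[traits], soil[svars],
      n_perm = config$ordination$n_perm %||% 999,
      seed = seed, standardize = standardize
    ))
  }

  summary <- list(
    seed = as.integer(seed),
    breadth = if (!is.null(breadth)) breadth,
    overlap_census = if (!is.null(ocensus)) ocensus,
    demography = demo,
    overall_decline = if (!is.null(decline)) decline$overall else NA,
    assessment = list(category = assessment$category,
                      criteria_code = assessment$criteria_code),
    psesp = psesp$psesp,
    ordination = if (!is.null(fit)) list(
      axis_explained_pct = unname(fit$axis_explained_pct),
      total_constrained_pct = fit$total_constrained_pct
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(iv_long)) {
      shown <- iv_summary(iv_long, se = se_conv)
      shown <- shown[shown$mean_iv >= min_iv, ]
      write_table(shown, file.path(out_dir, "importance_summary.tsv"))
      write_table(breadth, file.path(out_dir, "niche_breadth.tsv"))
      write_table(overlap, file.path(out_dir, "niche_overlap.md"),
                  format = "markdown")
      write_table(ocensus, file.path(out_dir, "overlap_census.tsv"))
    }
    write_table(demo, file.path(out_dir, "demography.tsv"))
    if (!is.null(selection)) {
      write_table(selection, file.path(out_dir, "forward_selection.tsv"), digits = 3)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }

  invisible(list(
    importance = iv_long, breadth = breadth, overlap = overlap,
    overlap_census = ocensus, demography = demo, decline = decline,
    assessment = assessment, psesp = psesp, ordination = fit,
    selection = selection, summary = summary, log = log_lines
  ))
}
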