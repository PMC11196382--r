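# Typed readers, writers and validation for the tabular formats the
# package consumes: plot surveys (plot x species observations), stage-
# structured censuses, and paired soil-chemistry / plant-trait tables.
# All files are UTF-8 delimited text with a mandatory header; comma is
# the default delimiter and tab is auto-detected.

# canonical column sets ------------------------------------------------

survey_columns <- c("plot_id", "species", "count", "mean_height_cm", "cover_pct")
census_columns <- c("site", "year", "total", "adult", "juvenile", "seedling")

#' Declared soil and trait variable vocabularies
#'
#' Soil variables: pH (unitless), EC (ms/cm), OM, N, P, K (g/kg), AN, AP,
#' AK, CEC, B, S (mg/kg), SM (percent).  Trait variables: plant height PHE
#' and crown diameter CD (cm) and the count-valued growth/flowering
#' indices (tillers NT, leaves NL, inflorescences NI, branches NB,
#' verticillasters NV, flowers NF, blooming flowers NBF, blooming flowers
#' per plant per day NBFPI, flowers per plant NFP).
#'
#' @return Character vector of recognised column names.
#' @export
soil_vocabulary <- function() {
  c("pH", "EC", "OM", "N", "P", "K", "AN", "AP", "AK", "CEC", "B", "S", "SM")
}

#' @rdname soil_vocabulary
#' @export
trait_vocabulary <- function() {
  c("PHE", "CD", "NT", "NL", "NI", "NB", "NV", "NF", "NBF", "NBFPI", "NFP")
}

# delimiter sniffing: tab wins if present in the header line
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) && grepl("\t", header)) "\t" else ","
}

read_delim_utf8 <- function(path, col_types = NULL) {
  if (!file.exists(path)) {
    stop_schema(paste0("file not found: '", path, "'"))
  }
  readr::read_delim(
    path,
    delim = detect_delim(path), col_types = col_types,
    locale = readr::locale(encoding = "UTF-8"), progress = FALSE,
    show_col_types = FALSE, trim_ws = TRUE
  )
}

require_columns <- function(tbl, wanted, path) {
  missing <- setdiff(wanted, names(tbl))
  if (length(missing)) {
    stop_schema(paste0(
      "'", path, "' is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
}

# plot surveys ----------------------------------------------------------

#' Read and validate a plot-survey table
#'
#' A plot survey records, per quadrat and species, the number of
#' individuals, their mean height (cm), and percent cover of the quadrat
#' area.  The expected columns are `plot_id`, `species`, `count`,
#' `mean_height_cm`, `cover_pct`; `schema` can remap nonstandard file
#' headers onto these names.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(cover_pct = "coverage")`.  Unmapped columns are taken verbatim.
#' @return A validated tibble (one row per plot x species observation,
#'   file order preserved), as produced by [validate_plot_survey()].
#' @seealso [validate_plot_survey()], [sim_community()]
#' @export
read_plot_survey <- function(path, schema = NULL) {
  tbl <- read_delim_utf8(path)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop_schema("`schema` must be a fully named character vector")
    }
    hit <- schema[schema %in% names(tbl)]
    miss <- setdiff(schema, names(tbl))
    if (length(miss)) {
      stop_schema(paste0(
        "'", path, "' is missing column(s) declared in the schema: ",
        paste(miss, collapse = ", ")
      ))
    }
    names(tbl)[match(hit, names(tbl))] <- names(hit)
  }
  require_columns(tbl, survey_columns, path)
  tbl <- tbl[survey_columns]
  validate_plot_survey(tbl)
}

#' Validate a plot-survey tibble
#'
#' Enforces the survey invariants: non-negative integer counts, positive
#' mean height wherever individuals were counted, cover within 0-100
#' percent, and unique (plot, species) pairs.
#'
#' @param tbl A data frame with the canonical survey columns.
#' @return The input as a tibble, invisibly unchanged, if valid.
#' @export
validate_plot_survey <- function(tbl) {
  tbl <- as_tibble(tbl)
  require_columns(tbl, survey_columns, "plot survey")
  if (!nrow(tbl)) stop_validation("plot survey has no observations")
  if (anyNA(tbl[survey_columns])) {
    stop_validation("plot survey contains missing values")
  }
  bad <- which(tbl$count < 0 | tbl$count != floor(tbl$count))
  if (length(bad)) {
    stop_validation(paste0(
      "count must be a non-negative integer; offending row(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  bad <- which(tbl$count > 0 & tbl$mean_height_cm <= 0)
  if (length(bad)) {
    stop_validation(paste0(
      "mean_height_cm must be positive where count > 0; offending row(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  bad <- which(tbl$cover_pct < 0 | tbl$cover_pct > 100)
  if (length(bad)) {
    stop_validation(paste0(
      "cover_pct must lie in [0, 100]; offending row(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  key <- paste(tbl$plot_id, tbl$species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop_validation(paste0(
      "duplicate (plot_id, species) pairs at row(s): ",
      paste(dup, collapse = ", ")
    ))
  }
  tbl
}

# censuses --------------------------------------------------------------

# "—"/"-"/"" parse as missing; "<N" parses as a censored upper bound
parse_census_cell <- function(x) {
  x <- trimws(as.character(x))
  miss <- is.na(x) | x %in% c("", "-", "—", "–", "NA")
  bound <- grepl("^<\\s*[0-9]+$", x)
  value <- suppressWarnings(as.integer(x))
  value[miss | bound] <- NA_integer_
  upper <- rep(NA_integer_, length(x))
  upper[bound] <- as.integer(sub("^<\\s*", "", x[bound]))
  plain <- !miss & !bound
  if (any(plain & is.na(value))) {
    stop_validation(paste0(
      "unparseable census count(s): ",
      paste(unique(x[plain & is.na(value)]), collapse = ", ")
    ))
  }
  if (any(value[plain] < 0, na.rm = TRUE)) {
    stop_validation("census counts must be non-negative")
  }
  list(value = value, upper = upper)
}

#' Read a stage-structured census table
#'
#' Expects columns `site`, `year`, `total`, `adult`, `juvenile`,
#' `seedling`.  Cells may be empty or an em/en dash (missing), or a
#' censored bound such as `<200` (historical reports that only bound the
#' count); bounds are returned in `total_upper_bound`, never as counts.
#' Where all three stage counts and the total are present the stage sum
#' must equal the total.
#'
#' @param path Path to a CSV/TSV census file.
#' @return A tibble sorted by (site, year) with integer columns `total`,
#'   `adult`, `juvenile`, `seedling` and `total_upper_bound`.
#' @seealso [census_totals()], [decline_flags()], [salvia_census()]
#' @export
read_census <- function(path) {
  tbl <- read_delim_utf8(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(tbl, census_columns, path)
  if (!nrow(tbl)) {
    return(tibble(
      site = character(), year = integer(), total = integer(),
      adult = integer(), juvenile = integer(), seedling = integer(),
      total_upper_bound = integer()
    ))
  }
  tot <- parse_census_cell(tbl$total)
  out <- tibble(
    site = as.character(tbl$site),
    year = as.integer(tbl$year),
    total = tot$value,
    adult = parse_census_cell(tbl$adult)$value,
    juvenile = parse_census_cell(tbl$juvenile)$value,
    seedling = parse_census_cell(tbl$seedling)$value,
    total_upper_bound = tot$upper
  )
  validate_census(out)
  arrange(out, .data$site, .data$year)
}

validate_census <- function(tbl) {
  full <- complete.cases(tbl[c("total", "adult", "juvenile", "seedling")])
  s <- tbl$adult + tbl$juvenile + tbl$seedling
  bad <- which(full & s != tbl$total)
  if (length(bad)) {
    stop_validation(paste0(
      "stage counts do not sum to the total for ",
      paste(sprintf("%s/%d (%d+%d+%d != %d)", tbl$site[bad], tbl$year[bad],
                    tbl$adult[bad], tbl$juvenile[bad], tbl$seedling[bad],
                    tbl$total[bad]), collapse = "; ")
    ))
  }
  invisible(tbl)
}

# soil-trait tables -----------------------------------------------------

#' Read a paired soil-chemistry and plant-trait table
#'
#' One row per sample, columns `sample_id`, `site`, then any subset of
#' the declared soil and trait vocabularies (see [soil_vocabulary()]).
#' Unrecognised columns and missing values are validation errors.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with attributes `soil_vars` and `trait_vars` naming
#'   the soil and trait columns found.
#' @seealso [sim_soil_traits()], [rda_fit()]
#' @export
read_soil_traits <- function(path) {
  tbl <- read_delim_utf8(path)
  require_columns(tbl, c("sample_id", "site"), path)
  vars <- setdiff(names(tbl), c("sample_id", "site"))
  unknown <- setdiff(vars, c(soil_vocabulary(), trait_vocabulary()))
  if (length(unknown)) {
    stop_validation(paste0(
      "column(s) outside the declared soil/trait vocabularies: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (anyNA(tbl)) stop_validation("soil-trait table contains missing values")
  tbl <- as_tibble(tbl)
  attr(tbl, "soil_vars") <- intersect(soil_vocabulary(), vars)
  attr(tbl, "trait_vars") <- intersect(trait_vocabulary(), vars)
  tbl
}

# writers ---------------------------------------------------------------

#' Write a result table deterministically
#'
#' Renders numeric columns with a fixed number of decimals (half-up) and
#' writes bytes that are identical across runs for identical input, in
#' TSV, CSV or pipe-table markdown.  An [overlap_matrix()] result is laid
#' out as a lower-triangular table with an em-dash diagonal, the
#' conventional presentation for niche-overlap matrices.
#'
#' @param x A data frame, or a matrix of class `overlap_matrix`.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"csv"`, `"markdown"`.
#' @param digits Decimals used for numeric columns (default 2, the usual
#'   precision of published community tables).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("tsv", "csv", "markdown"),
                        digits = 2) {
  format <- match.arg(format)
  if (inherits(x, "overlap_matrix")) {
    lines <- format_overlap_lines(x, format = format, digits = digits)
  } else {
    if (!is.data.frame(x)) stop_param("`x` must be a data frame or overlap_matrix")
    cells <- lapply(x, function(col) {
      if (is.numeric(col) && !is.integer(col)) fmt_num(col, digits)
      else {
        out <- as.character(col)
        out[is.na(out)] <- ""
        out
      }
    })
    rows <- rbind(names(x), do.call(cbind, cells))
    lines <- render_rows(rows, format)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

render_rows <- function(rows, format) {
  if (format == "markdown") {
    body <- apply(rows, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    sep <- paste0("|", paste(rep("---", ncol(rows)), collapse = "|"), "|")
    c(body[1], sep, body[-1])
  } else {
    delim <- if (format == "tsv") "\t" else ","
    apply(rows, 1, paste, collapse = delim)
  }
}

format_overlap_lines <- function(m, format = "markdown", digits = 2) {
  n <- nrow(m)
  rows <- matrix("", nrow = n + 1, ncol = n + 1)
  rows[1, ] <- c("No.", as.character(seq_len(n)))
  for (i in seq_len(n)) {
    rows[i + 1, 1] <- as.character(i)
    if (i > 1) {
      rows[i + 1, 2:i] <- fmt_num(m[i, seq_len(i - 1)], digits)
    }
    rows[i + 1, i + 1] <- "—"
  }
  render_rows(rows, format)
}
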