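read_table_file <- function(path, what) {
  if (!file.exists(path)) {
    abort(paste0("Input file for ", what, " not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading spreadsheets requires the 'readxl' package.")
    }
    tibble::as_tibble(readxl::read_excel(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read the standard input tables
#'
#' CSV (or spreadsheet) readers for the pipeline's input schemas. Each
#' validates its mandatory columns and value constraints; empty cells are
#' missing values.
#'
#' @param path file path.
#' @return A validated tibble.
#' @name readers
#' @export
read_composition_csv <- function(path) {
  validate_composition(read_table_file(path, "food composition"))
}

#' @rdname readers
#' @export
read_bouts_csv <- function(path) {
  validate_bouts(read_table_file(path, "feeding bouts"))
}

#' @rdname readers
#' @export
read_rates_csv <- function(path) {
  rates <- read_table_file(path, "intake rates")
  need <- c("food_id", "units", "duration_s")
  miss <- setdiff(need, names(rates))
  if (length(miss)) {
    abort(paste0("Rate table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(rates$units < 0) || any(rates$duration_s <= 0)) {
    abort("Rate records need `units` >= 0 and `duration_s` > 0.")
  }
  rates
}

#' @rdname readers
#' @export
read_handling_csv <- function(path) {
  h <- read_table_file(path, "food handling")
  miss <- setdiff(c("food_id", "unit_mass_g"), names(h))
  if (length(miss)) {
    abort(paste0("Handling table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  h
}

#' @rdname readers
#' @export
read_body_mass_csv <- function(path) {
  bm <- read_table_file(path, "body mass")
  miss <- setdiff(c("focal_id", "mass_kg"), names(bm))
  if (length(miss)) {
    abort(paste0("Body-mass table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bm
}

#' Write a derived composition table
#'
#' @param derived output of [derive_composition()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_derived_composition_csv <- function(derived, path) {
  cols <- c("food_id", "species", "genus", "part_code", chemistry_cols(),
            "ap", "tnc", "energy_kj_per_g", "ap_npe",
            "share_protein", "share_fat", "share_carb")
  if ("provenance" %in% names(derived)) cols <- c(cols, "provenance")
  readr::write_csv(derived[, intersect(cols, names(derived))], path)
  invisible(path)
}

#' Load an externally produced daily-intake table
#'
#' Reads a per-focal-day archive (CSV or spreadsheet) into the daily-intake
#' schema used throughout the package, so that previously published per-day
#' data can be pushed through the same aggregation, geometry and modelling
#' stages. Column names that differ from the package schema are absorbed by
#' `mapping`; unmapped extra columns are preserved. Missing mandatory columns
#' are reported by name; the row count is logged.
#'
#' @param path file path (`.csv`, `.xlsx`).
#' @param mapping named character vector, `schema_name = "file column name"`,
#'   overriding the default one-to-one name match.
#' @return A daily-intake tibble (season and lean flags recomputed from the
#'   period if absent).
#' @export
read_daily_intakes <- function(path, mapping = NULL) {
  raw <- read_table_file(path, "daily intakes")
  if (nrow(raw) == 0) abort(paste0("Daily-intake file is empty: ", path))
  if (!is.null(mapping)) {
    for (schema_name in names(mapping)) {
      file_name <- mapping[[schema_name]]
      if (!file_name %in% names(raw)) {
        abort(paste0("Mapped column '", file_name, "' not found in file."))
      }
      names(raw)[names(raw) == file_name] <- schema_name
    }
  }
  mandatory <- c("focal_id", "group_id", "period", "energy_kj", "ap_g")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    abort(paste0("Daily-intake file is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"date" %in% names(raw)) {
    raw$date <- paste0("row", seq_len(nrow(raw)))
  }
  raw$period <- as.integer(raw$period)
  if (!"season" %in% names(raw)) raw$season <- assign_season(raw$period)
  if (!"lean" %in% names(raw)) raw$lean <- is_lean_season(raw$season)
  inform(paste0("Loaded ", nrow(raw), " focal-day rows from ", path))
  raw
}

#' Write a daily-intake table
#'
#' @param daily a daily-intake tibble.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_intakes_csv <- function(daily, path) {
  readr::write_csv(daily, path)
  invisible(path)
}
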