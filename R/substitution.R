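#' Fill in chemistry for an unassayed food
#'
#' Implements the substitution hierarchy used when a food in the diet was not
#' chemically assayed: use the record itself if measured (`provenance =
#' "direct"`); otherwise the unweighted mean over measured congeners (same
#' genus, same plant part; `"congener"`); otherwise the mean over all measured
#' foods of that plant part (`"part_average"`). Measured young-leaf records
#' lacking a fat assay have fat filled with the mean fat of measured
#' young-leaf samples (and analogously for other parts) before any averaging.
#'
#' @param food_id identifier of the food to resolve.
#' @param library a composition table containing at least one record (possibly
#'   with missing chemistry) for `food_id`, plus the measured records that can
#'   donate values. See [validate_composition()].
#' @param constants unused; accepted for interface symmetry.
#'
#' @return A one-row tibble: the resolved record with complete chemistry and a
#'   `provenance` column.
#' @export
substitute_composition <- function(food_id, library, constants = NULL) {
  library <- fill_missing_fat(validate_composition(library))
  rec <- library[library$food_id == food_id, ]
  if (nrow(rec) == 0) {
    abort(paste0("Food '", food_id, "' is not in the composition library."))
  }
  rec <- rec[1, ]
  if (isTRUE(rec$measured)) {
    rec$provenance <- "direct"
    return(rec)
  }
  measured <- library[library$measured & library$food_id != food_id, ]
  congeners <- measured[measured$genus == rec$genus &
                          measured$part_code == rec$part_code, ]
  if (nrow(congeners) > 0) {
    donor <- congeners
    rec$provenance <- "congener"
  } else {
    donor <- measured[measured$part_code == rec$part_code, ]
    rec$provenance <- "part_average"
  }
  if (nrow(donor) == 0) {
    abort(paste0("Food '", food_id, "' cannot be resolved: no measured ",
                 "record for part code '", rec$part_code, "'."))
  }
  for (nm in chemistry_cols()) {
    rec[[nm]] <- mean(donor[[nm]])
  }
  rec$measured <- FALSE
  rec
}

# Fill missing fat in measured records with the measured mean fat of the same
# plant part (the convention used for young-leaf samples not assayed for fat).
fill_missing_fat <- function(library) {
  idx <- which(library$measured & is.na(library$fat))
  if (!length(idx)) return(library)
  for (i in idx) {
    part <- library$part_code[i]
    donors <- library$fat[library$measured & library$part_code == part &
                            !is.na(library$fat)]
    if (!length(donors)) {
      abort(paste0("Cannot fill missing fat for part code '", part,
                   "': no measured fat values for that part."))
    }
    library$fat[i] <- mean(donors)
  }
  library
}

#' Resolve a whole composition library
#'
#' Applies [substitute_composition()] to every food in the library, returning
#' a complete table with a `provenance` column recording how each record was
#' obtained.
#'
#' @inheritParams substitute_composition
#' @return A tibble with one complete-chemistry row per food.
#' @export
resolve_compositions <- function(library, constants = NULL) {
  library <- validate_composition(library)
  rows <- lapply(library$food_id, substitute_composition, library = library)
  dplyr::bind_rows(rows)
}
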