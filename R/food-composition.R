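#' Physiological fuel values and digestion constants
#'
#' Constants used to convert macronutrient masses to metabolizable energy and
#' to scale intakes to metabolic body mass. Protein and carbohydrate carry
#' 16.736 kJ/g, fat 37.656 kJ/g, and fermentable fiber 12.552 kJ/g discounted
#' by the digestibility of cellulose (`dig_cell` = 0.3911, applied to
#' ADF - lignin) and hemicellulose (`dig_hc` = 0.5197, applied to NDF - ADF).
#' Energy intakes are scaled by body mass raised to `metabolic_exponent`
#' (0.762).
#'
#' @param ... named overrides for individual constants (all must be positive;
#'   digestibilities and the exponent must lie in (0, 1]).
#'
#' @return A named list of class `fuel_constants`.
#' @export
#' @examples
#' fuel_constants()$kj_fat
fuel_constants <- function(...) {
  const <- list(
    kj_protein = 16.736,
    kj_tnc = 16.736,
    kj_fat = 37.656,
    kj_fiber = 12.552,
    dig_cell = 0.3911,
    dig_hc = 0.5197,
    metabolic_exponent = 0.762
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(const))
    if (length(bad)) {
      abort(paste0("Unknown fuel constant(s): ", paste(bad, collapse = ", ")))
    }
    const <- modifyList(const, dots)
  }
  vals <- unlist(const)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All fuel constants must be positive and finite.")
  }
  if (const$dig_cell > 1 || const$dig_hc > 1 || const$metabolic_exponent > 1) {
    abort("Digestibilities and the metabolic exponent must not exceed 1.")
  }
  structure(const, class = "fuel_constants")
}

#' Plant part codes
#'
#' The eight plant part/stage codes used throughout: young leaf (YL), shoot
#' (SH), flower (FL), flower bud (BD), fruit without seed (F), fruit with seed
#' (FSD), seed (SD) and unripe fruit with seed (URFSD).
#'
#' @name part_codes
#' @return `part_codes()` returns all eight codes; `fruit_seed_parts()` the
#'   subset counted as fruit/seed when computing the frugivory fraction.
#' @export
part_codes <- function() {
  c("YL", "SH", "FL", "BD", "F", "FSD", "SD", "URFSD")
}

#' @rdname part_codes
#' @export
fruit_seed_parts <- function() {
  c("F", "FSD", "SD", "URFSD")
}

chemistry_cols <- function() {
  c("cp", "adicp", "fat", "ash", "ndf", "adf", "lignin")
}

check_percent <- function(x, name, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad)) {
    abort(paste0("`", name, "` must lie in [0, 100]; offending values: ",
                 paste(head(x[bad], 3), collapse = ", ")))
  }
  if (!allow_na && anyNA(x)) {
    abort(paste0("`", name, "` contains missing values."))
  }
  invisible(x)
}

#' Available protein
#'
#' Available (digestible) protein is crude protein minus the acid
#' detergent-insoluble crude protein bound to fiber.
#'
#' @param cp crude protein, % dry matter.
#' @param adicp acid detergent-insoluble crude protein, % dry matter.
#' @param food_id optional identifiers used in error messages.
#'
#' @return Available protein, % dry matter.
#' @export
#' @examples
#' available_protein(10, 2)
available_protein <- function(cp, adicp, food_id = NULL) {
  check_percent(cp, "cp")
  check_percent(adicp, "adicp")
  bad <- adicp > cp
  if (any(bad)) {
    who <- if (is.null(food_id)) which(bad) else food_id[bad]
    abort(paste0("ADICP exceeds crude protein for: ",
                 paste(head(who, 5), collapse = ", ")))
  }
  cp - adicp
}

#' Total non-structural carbohydrates by difference
#'
#' TNC is what remains of dry matter after fat, available protein, ash and
#' NDF: `100 - (fat + (cp - adicp) + ash + ndf)`. Assay rounding can push the
#' difference slightly negative; such values are clamped to zero with a
#' warning.
#'
#' @inheritParams available_protein
#' @param fat,ash,ndf concentrations, % dry matter.
#'
#' @return TNC, % dry matter (never negative).
#' @export
#' @examples
#' compute_tnc(fat = 5, cp = 10, adicp = 2, ash = 5, ndf = 40)
compute_tnc <- function(fat, cp, adicp, ash, ndf, food_id = NULL) {
  for (nm in c("fat", "cp", "adicp", "ash", "ndf")) {
    check_percent(get(nm), nm)
  }
  tnc <- 100 - (fat + (cp - adicp) + ash + ndf)
  neg <- tnc < 0
  if (any(neg)) {
    who <- if (is.null(food_id)) which(neg) else food_id[neg]
    warn(paste0("TNC by difference was negative and clamped to 0 for: ",
                paste(head(who, 5), collapse = ", ")))
    tnc[neg] <- 0
  }
  tnc
}

check_fiber <- function(ndf, adf, lignin) {
  check_percent(ndf, "ndf")
  check_percent(adf, "adf")
  check_percent(lignin, "lignin")
  if (any(adf > ndf)) abort("ADF exceeds NDF.")
  if (any(lignin > adf)) abort("Lignin exceeds ADF.")
  invisible(NULL)
}

# kJ per g DM contributed by fermentable fiber (digestible cellulose and
# hemicellulose fractions).
fiber_energy <- function(ndf, adf, lignin, constants = fuel_constants()) {
  constants$dig_cell * (adf - lignin) / 100 * constants$kj_fiber +
    constants$dig_hc * (ndf - adf) / 100 * constants$kj_fiber
}

#' Energy density of a food from physiological fuel values
#'
#' Sums the fuel values of available protein, TNC, fat and the digestible
#' cellulose and hemicellulose fractions of fiber:
#' `E = AP*16.736 + TNC*16.736 + Fat*37.656 +
#'  dig_cell*(ADF - lignin)*12.552 + dig_hc*(NDF - ADF)*12.552`,
#' with concentrations expressed as g/g (percent / 100) so the result is in
#' kJ per g dry matter.
#'
#' @param ap available protein, % dry matter.
#' @param tnc total non-structural carbohydrates, % dry matter.
#' @param fat,ndf,adf,lignin concentrations, % dry matter.
#' @param constants a [fuel_constants()] list.
#'
#' @return Energy density, kJ per g dry matter.
#' @export
#' @examples
#' energy_density(ap = 10, tnc = 40, fat = 5, ndf = 45, adf = 30, lignin = 10)
energy_density <- function(ap, tnc, fat, ndf, adf, lignin,
                           constants = fuel_constants()) {
  check_percent(ap, "ap")
  check_percent(tnc, "tnc")
  check_percent(fat, "fat")
  check_fiber(ndf, adf, lignin)
  ap / 100 * constants$kj_protein +
    tnc / 100 * constants$kj_tnc +
    fat / 100 * constants$kj_fat +
    fiber_energy(ndf, adf, lignin, constants)
}

#' Ratio of available-protein energy to non-protein energy for a food
#'
#' Non-protein energy (NPE) comprises TNC, fat and the digestible-fiber
#' energy. The ratio depends only on composition, not on the amount of food.
#'
#' @inheritParams energy_density
#'
#' @return AP:NPE, dimensionless.
#' @export
#' @examples
#' food_ap_npe(ap = 10, tnc = 50, fat = 5, ndf = 30, adf = 20, lignin = 8)
food_ap_npe <- function(ap, tnc, fat, ndf, adf, lignin,
                        constants = fuel_constants()) {
  check_percent(ap, "ap")
  check_percent(tnc, "tnc")
  check_percent(fat, "fat")
  check_fiber(ndf, adf, lignin)
  ap_kj <- ap / 100 * constants$kj_protein
  npe_kj <- tnc / 100 * constants$kj_tnc + fat / 100 * constants$kj_fat +
    fiber_energy(ndf, adf, lignin, constants)
  if (any(npe_kj == 0 & ap_kj > 0)) {
    abort("AP:NPE is undefined: non-protein energy is zero while AP > 0.")
  }
  if (any(npe_kj == 0 & ap_kj == 0)) {
    abort("AP:NPE is undefined: both AP and non-protein energy are zero.")
  }
  ap_kj / npe_kj
}

#' Percentage contributions of protein, fat and carbohydrate to
#' fiber-free macronutrient energy
#'
#' @inheritParams energy_density
#' @return A tibble with columns `share_protein`, `share_fat`, `share_carb`
#'   summing to 100.
#' @export
macronutrient_energy_shares <- function(ap, tnc, fat,
                                        constants = fuel_constants()) {
  p <- ap / 100 * constants$kj_protein
  f <- fat / 100 * constants$kj_fat
  c_ <- tnc / 100 * constants$kj_tnc
  tot <- p + f + c_
  if (any(tot <= 0)) abort("Fiber-free macronutrient energy must be positive.")
  tibble::tibble(
    share_protein = 100 * p / tot,
    share_fat = 100 * f / tot,
    share_carb = 100 * c_ / tot
  )
}

#' Validate a food composition table
#'
#' Checks the schema (`food_id`, `species`, `genus`, `part_code` and the seven
#' chemistry columns), the part-code taxonomy, concentration ranges and the
#' fiber ordering `ndf >= adf >= lignin` and `cp >= adicp`. Chemistry may be
#' missing (`NA`) for unassayed foods; those rows are completed by
#' [resolve_compositions()].
#'
#' @param comp a data frame of food composition records.
#' @return `comp` as a tibble, invisibly validated, with a logical `measured`
#'   column (added if absent: a record is measured when `cp` is non-missing).
#' @export
validate_composition <- function(comp) {
  comp <- tibble::as_tibble(comp)
  need <- c("food_id", "species", "genus", "part_code", chemistry_cols())
  miss <- setdiff(need, names(comp))
  if (length(miss)) {
    abort(paste0("Composition table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad_part <- !comp$part_code %in% part_codes()
  if (any(bad_part)) {
    abort(paste0("Unknown part code(s): ",
                 paste(unique(comp$part_code[bad_part]), collapse = ", ")))
  }
  if (!"measured" %in% names(comp)) comp$measured <- !is.na(comp$cp)
  for (nm in chemistry_cols()) check_percent(comp[[nm]], nm, allow_na = TRUE)
  m <- comp[comp$measured, ]
  if (nrow(m)) {
    if (anyNA(m$cp) || anyNA(m$adicp) || anyNA(m$ash) || anyNA(m$ndf) ||
        anyNA(m$adf) || anyNA(m$lignin)) {
      abort("Measured records may only have missing `fat`.")
    }
    check_fiber(m$ndf, m$adf, m$lignin)
    if (any(m$adicp > m$cp)) {
      abort(paste0("ADICP exceeds crude protein for: ",
                   paste(m$food_id[m$adicp > m$cp], collapse = ", ")))
    }
  }
  comp
}

#' Derive nutritional quantities for measured foods
#'
#' Adds available protein, TNC (by difference), energy density, the per-food
#' AP:NPE ratio and fiber-free macronutrient energy shares to a composition
#' table. All records must have complete chemistry; run
#' [resolve_compositions()] first if the library contains unassayed foods.
#'
#' @param comp a validated composition table (see [validate_composition()]).
#' @param constants a [fuel_constants()] list.
#' @return The input tibble with columns `ap`, `tnc`, `energy_kj_per_g`,
#'   `ap_npe`, `share_protein`, `share_fat`, `share_carb` appended.
#' @export
derive_composition <- function(comp, constants = fuel_constants()) {
  comp <- validate_composition(comp)
  if (anyNA(comp[chemistry_cols()])) {
    abort("Chemistry is incomplete; call resolve_compositions() first.")
  }
  comp$ap <- available_protein(comp$cp, comp$adicp, comp$food_id)
  comp$tnc <- compute_tnc(comp$fat, comp$cp, comp$adicp, comp$ash, comp$ndf,
                          comp$food_id)
  comp$energy_kj_per_g <- energy_density(comp$ap, comp$tnc, comp$fat,
                                         comp$ndf, comp$adf, comp$lignin,
                                         constants)
  comp$ap_npe <- food_ap_npe(comp$ap, comp$tnc, comp$fat, comp$ndf, comp$adf,
                             comp$lignin, constants)
  shares <- macronutrient_energy_shares(comp$ap, comp$tnc, comp$fat, constants)
  dplyr::bind_cols(comp, shares)
}
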