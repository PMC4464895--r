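#' Map data collection periods to seasons
#'
#' The twelve collection periods fall into five seasons: periods 1-2 form
#' season 1, 3-5 season 2, 6-8 season 3, 9-10 season 4 and 11-12 season 5.
#' Seasons 1, 4 and 5 (cool, dry, low food availability) are the lean season;
#' seasons 2 and 3 the abundant season.
#'
#' @param period integer vector of collection periods (1-12).
#' @return `assign_season()`: integer season (1-5); `is_lean_season()`:
#'   logical, `TRUE` for lean seasons.
#' @export
#' @examples
#' assign_season(1:12)
assign_season <- function(period) {
  if (anyNA(period) || any(period != as.integer(period)) ||
      any(period < 1) || any(period > 12)) {
    abort("`period` must be an integer in 1..12.")
  }
  season_map <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L)
  season_map[as.integer(period)]
}

#' @rdname assign_season
#' @param season integer season (1-5).
#' @export
is_lean_season <- function(season) {
  if (any(!season %in% 1:5)) abort("`season` must be in 1..5.")
  season %in% c(1L, 4L, 5L)
}

#' Pool intake-rate records for one food
#'
#' Intake rates are pooled across individuals and sites as total units
#' consumed divided by total observed time, weighting each record by its
#' duration. Records in `count_per_interval` mode (units counted in timed
#' intervals) and `per_item_duration` mode (items with summed handling time)
#' pool identically.
#'
#' @param records a data frame with columns `units` and `duration_s` (all for
#'   the same food).
#' @return Pooled rate, units per second.
#' @export
#' @examples
#' pool_intake_rate(data.frame(units = c(10, 20), duration_s = c(60, 40)))
pool_intake_rate <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("No intake-rate records to pool.")
  }
  if (any(records$units < 0) || any(records$duration_s <= 0)) {
    abort("Intake-rate records need `units` >= 0 and `duration_s` > 0.")
  }
  sum(records$units) / sum(records$duration_s)
}

#' Pool intake rates for every food in a rate table
#'
#' @param rates a data frame with columns `food_id`, `units`, `duration_s`
#'   (and optionally `mode`).
#' @return A tibble with columns `food_id` and `rate_units_per_s`.
#' @export
pool_intake_rates <- function(rates) {
  rates |>
    dplyr::group_by(.data$food_id) |>
    dplyr::summarise(
      rate_units_per_s = sum(.data$units) / sum(.data$duration_s),
      .groups = "drop"
    )
}

#' Scale energy intake to metabolic body mass
#'
#' @param energy_kj daily energy intake, kJ.
#' @param mass_kg body mass, kg.
#' @param exponent metabolic scaling exponent (default 0.762).
#' @return Energy intake in kJ per kg^exponent per day.
#' @export
#' @examples
#' scale_energy(1673.6, 1)
scale_energy <- function(energy_kj, mass_kg,
                         exponent = fuel_constants()$metabolic_exponent) {
  if (any(!is.na(mass_kg) & mass_kg <= 0)) {
    abort("`mass_kg` must be positive.")
  }
  energy_kj / mass_kg^exponent
}

#' Convert a protein requirement to kJ per day
#'
#' Converts a mass-specific protein requirement (g per kg body mass per day)
#' to an energy-equivalent requirement for an animal of a given mass, using
#' the protein fuel value of 16.736 kJ/g. For example, the 1.8-2.8 g/kg/day
#' range typically cited for adult primates corresponds to 151-234 kJ/day for
#' a 5-kg animal.
#'
#' @param g_per_kg requirement in g per kg body mass per day.
#' @param mass_kg body mass, kg.
#' @param constants a [fuel_constants()] list.
#' @return Requirement in kJ/day, rounded to the nearest kJ.
#' @export
#' @examples
#' protein_requirement_kj(2.8, 5)
protein_requirement_kj <- function(g_per_kg, mass_kg,
                                   constants = fuel_constants()) {
  if (any(g_per_kg <= 0) || any(mass_kg <= 0)) {
    abort("`g_per_kg` and `mass_kg` must be positive.")
  }
  round(g_per_kg * mass_kg * constants$kj_protein)
}

validate_bouts <- function(bouts) {
  bouts <- tibble::as_tibble(bouts)
  need <- c("focal_id", "group_id", "date", "period", "food_id", "duration_s")
  miss <- setdiff(need, names(bouts))
  if (length(miss)) {
    abort(paste0("Bout table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"is_soil" %in% names(bouts)) bouts$is_soil <- FALSE
  if (nrow(bouts)) {
    if (any(bouts$duration_s <= 0)) abort("Bout durations must be positive.")
    assign_season(bouts$period)
  }
  bouts
}

# Per-food conversion table: pooled rate, unit mass, conversion factor,
# derived chemistry and g/s -> per-second nutrient flux for each food.
build_food_flux <- function(food_ids, rates, handling, compositions,
                            constants) {
  comp <- resolve_compositions(compositions, constants)
  comp <- derive_composition(comp, constants)
  pooled <- pool_intake_rates(rates)
  # rate fallback: foods with no rate records inherit the pooled rate of all
  # observed foods sharing their plant part
  missing_rate <- setdiff(food_ids, pooled$food_id)
  if (length(missing_rate)) {
    part_of <- setNames(comp$part_code, comp$food_id)
    rate_part <- merge(rates, comp[, c("food_id", "part_code")],
                       by = "food_id")
    extra <- lapply(missing_rate, function(fid) {
      part <- part_of[[fid]]
      if (is.null(part)) {
        abort(paste0("Food '", fid, "' has no composition record."))
      }
      recs <- rate_part[rate_part$part_code == part, ]
      if (nrow(recs) == 0) {
        abort(paste0("No intake rate for food '", fid,
                     "' and no rates for part code '", part, "'."))
      }
      tibble::tibble(food_id = fid,
                     rate_units_per_s = pool_intake_rate(recs))
    })
    inform(paste0("Intake rate substituted from part-code pool for: ",
                  paste(missing_rate, collapse = ", ")))
    pooled <- dplyr::bind_rows(pooled, dplyr::bind_rows(extra))
  }
  handling <- tibble::as_tibble(handling)
  if (!"conversion_factor" %in% names(handling)) {
    handling$conversion_factor <- 1
  }
  handling$conversion_factor[is.na(handling$conversion_factor)] <- 1
  if (any(handling$unit_mass_g <= 0) || any(handling$conversion_factor <= 0)) {
    abort("Unit masses and conversion factors must be positive.")
  }
  miss_h <- setdiff(food_ids, handling$food_id)
  if (length(miss_h)) {
    abort(paste0("No handling (unit mass) record for: ",
                 paste(miss_h, collapse = ", ")))
  }
  flux <- comp |>
    dplyr::inner_join(pooled, by = "food_id") |>
    dplyr::inner_join(handling[, c("food_id", "unit_mass_g",
                                   "conversion_factor")], by = "food_id")
  flux$g_per_s <- flux$rate_units_per_s * flux$unit_mass_g *
    flux$conversion_factor
  flux$is_fruit_seed <- flux$part_code %in% fruit_seed_parts()
  flux
}

#' Daily intakes from timed feeding bouts
#'
#' Implements the focal-animal daily intake estimator: for each bout,
#' intake of quantity y is `duration * rate * unit_mass * conversion *
#' concentration` (concentration in g/g for nutrients, kJ/g for energy), and
#' a focal-day's intake is the sum over its bouts. Soil bouts are excluded
#' from all nutritional sums but tallied in a `soil_audit` attribute. Foods
#' without an assayed composition are completed by the substitution hierarchy
#' ([resolve_compositions()]); foods without intake-rate records inherit the
#' pooled rate of their plant part.
#'
#' @param bouts feeding bouts: `focal_id`, `group_id`, `date`, `period`,
#'   `food_id`, `duration_s`, optional `is_soil`.
#' @param rates intake-rate records: `food_id`, `units`, `duration_s`.
#' @param handling unit masses: `food_id`, `unit_mass_g`, optional
#'   `conversion_factor` (default 1).
#' @param compositions food composition library (see
#'   [validate_composition()]).
#' @param body_mass optional body masses: `focal_id`, `mass_kg`; focal animals
#'   without a record receive their group's mean mass.
#' @param constants a [fuel_constants()] list.
#'
#' @return A tibble with one row per focal-day: feeding time, dry mass,
#'   fruit/seed mass fraction, energy, macronutrient and fiber intakes (g),
#'   the day's AP:NPE ratio, and intakes scaled to (metabolic) body mass.
#'   The excluded soil-feeding time is attached as attribute `soil_audit`.
#' @export
compute_daily_intakes <- function(bouts, rates, handling, compositions,
                                  body_mass = NULL,
                                  constants = fuel_constants()) {
  bouts <- validate_bouts(bouts)
  if (nrow(bouts) == 0) {
    return(empty_daily_intake())
  }
  soil_audit <- bouts |>
    dplyr::filter(.data$is_soil) |>
    dplyr::group_by(.data$focal_id, .data$date) |>
    dplyr::summarise(soil_s = sum(.data$duration_s), .groups = "drop")
  food_bouts <- dplyr::filter(bouts, !.data$is_soil)
  flux <- build_food_flux(unique(food_bouts$food_id), rates, handling,
                          compositions, constants)
  per_bout <- food_bouts |>
    dplyr::inner_join(
      flux[, c("food_id", "g_per_s", "energy_kj_per_g", "ap", "fat", "tnc",
               "ndf", "adf", "lignin", "is_fruit_seed")],
      by = "food_id"
    ) |>
    dplyr::mutate(
      grams = .data$duration_s * .data$g_per_s,
      energy_kj = .data$grams * .data$energy_kj_per_g,
      ap_g = .data$grams * .data$ap / 100,
      fat_g = .data$grams * .data$fat / 100,
      tnc_g = .data$grams * .data$tnc / 100,
      ndf_g = .data$grams * .data$ndf / 100,
      adf_g = .data$grams * .data$adf / 100,
      lignin_g = .data$grams * .data$lignin / 100
    )
  daily <- per_bout |>
    dplyr::group_by(.data$focal_id, .data$group_id, .data$date,
                    .data$period) |>
    dplyr::summarise(
      feeding_time_s = sum(.data$duration_s),
      dry_mass_g = sum(.data$grams),
      frac_mass_fruit_seed =
        ifelse(sum(.data$grams) > 0,
               sum(.data$grams[.data$is_fruit_seed]) / sum(.data$grams),
               NA_real_),
      energy_kj = sum(.data$energy_kj),
      ap_g = sum(.data$ap_g),
      fat_g = sum(.data$fat_g),
      tnc_g = sum(.data$tnc_g),
      ndf_g = sum(.data$ndf_g),
      adf_g = sum(.data$adf_g),
      lignin_g = sum(.data$lignin_g),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      season = assign_season(.data$period),
      lean = is_lean_season(.data$season),
      ap_npe = daily_ap_npe(.data$ap_g, .data$fat_g, .data$tnc_g,
                            .data$ndf_g, .data$adf_g, .data$lignin_g,
                            constants)
    )
  if (any(daily$dry_mass_g == 0 & daily$feeding_time_s > 0)) {
    warn("Some focal-days have feeding time but zero ingested mass; their AP:NPE is reported as missing.")
  }
  daily <- attach_body_mass(daily, body_mass, constants)
  daily <- daily[, daily_intake_cols()]
  attr(daily, "soil_audit") <- soil_audit
  daily
}

#' Day-level AP:NPE ratio from gram intakes
#'
#' @param ap_g,fat_g,tnc_g,ndf_g,adf_g,lignin_g daily intakes in grams.
#' @param constants a [fuel_constants()] list.
#' @return AP:NPE (NA where non-protein energy is zero).
#' @export
daily_ap_npe <- function(ap_g, fat_g, tnc_g, ndf_g, adf_g, lignin_g,
                         constants = fuel_constants()) {
  ap_kj <- ap_g * constants$kj_protein
  fiber_kj <- constants$dig_cell * (adf_g - lignin_g) * constants$kj_fiber +
    constants$dig_hc * (ndf_g - adf_g) * constants$kj_fiber
  npe_kj <- tnc_g * constants$kj_tnc + fat_g * constants$kj_fat + fiber_kj
  ifelse(npe_kj > 0, ap_kj / npe_kj, NA_real_)
}

daily_intake_cols <- function() {
  c("focal_id", "group_id", "date", "period", "season", "lean",
    "feeding_time_s", "dry_mass_g", "frac_mass_fruit_seed", "energy_kj",
    "ap_g", "fat_g", "tnc_g", "ndf_g", "adf_g", "lignin_g", "ap_npe",
    "mass_kg", "energy_per_mbm", "ap_per_bm")
}

empty_daily_intake <- function() {
  out <- tibble::tibble(
    focal_id = character(), group_id = character(), date = character(),
    period = integer(), season = integer(), lean = logical(),
    feeding_time_s = numeric(), dry_mass_g = numeric(),
    frac_mass_fruit_seed = numeric(), energy_kj = numeric(),
    ap_g = numeric(), fat_g = numeric(), tnc_g = numeric(),
    ndf_g = numeric(), adf_g = numeric(), lignin_g = numeric(),
    ap_npe = numeric(), mass_kg = numeric(), energy_per_mbm = numeric(),
    ap_per_bm = numeric()
  )
  attr(out, "soil_audit") <- tibble::tibble(focal_id = character(),
                                            date = character(),
                                            soil_s = numeric())
  out
}

attach_body_mass <- function(daily, body_mass, constants) {
  if (is.null(body_mass)) {
    daily$mass_kg <- NA_real_
    daily$energy_per_mbm <- NA_real_
    daily$ap_per_bm <- NA_real_
    return(daily)
  }
  body_mass <- tibble::as_tibble(body_mass)
  if (any(body_mass$mass_kg <= 0)) abort("Body masses must be positive.")
  daily <- dplyr::left_join(daily,
                            body_mass[, c("focal_id", "mass_kg")],
                            by = "focal_id")
  # focal animals never captured: use the mean mass of their group's members
  if (anyNA(daily$mass_kg)) {
    grp_mean <- daily |>
      dplyr::distinct(.data$focal_id, .data$group_id, .data$mass_kg) |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(grp_mass = mean(.data$mass_kg, na.rm = TRUE),
                       .groups = "drop")
    daily <- dplyr::left_join(daily, grp_mean, by = "group_id")
    filled <- is.na(daily$mass_kg) & is.finite(daily$grp_mass)
    if (any(filled)) {
      inform(paste0("Body mass substituted with group mean for: ",
                    paste(unique(daily$focal_id[is.na(daily$mass_kg)]),
                          collapse = ", ")))
    }
    daily$mass_kg[filled] <- daily$grp_mass[filled]
    daily$grp_mass <- NULL
  }
  daily$energy_per_mbm <- scale_energy(daily$energy_kj, daily$mass_kg,
                                       constants$metabolic_exponent)
  daily$ap_per_bm <- daily$ap_g / daily$mass_kg
  daily
}

#' Daily intake for a single focal-day
#'
#' Convenience wrapper around [compute_daily_intakes()] for one
#' (focal, date) combination. A day with no bouts yields an all-zero record
#' with missing AP:NPE.
#'
#' @inheritParams compute_daily_intakes
#' @param focal_id,group_id,date,period identify the focal-day (used when
#'   `bouts` is empty).
#' @return A one-row daily-intake tibble.
#' @export
daily_intake <- function(bouts, rates, handling, compositions,
                         body_mass = NULL, constants = fuel_constants(),
                         focal_id = NULL, group_id = NULL, date = NULL,
                         period = NULL) {
  bouts <- validate_bouts(bouts)
  if (nrow(bouts) == 0) {
    if (is.null(focal_id) || is.null(period)) {
      abort("For an empty day, supply focal_id, group_id, date and period.")
    }
    out <- empty_daily_intake()
    out[1, ] <- NA
    out$focal_id <- focal_id
    out$group_id <- group_id %||% NA_character_
    out$date <- date %||% NA_character_
    out$period <- as.integer(period)
    out$season <- assign_season(period)
    out$lean <- is_lean_season(out$season)
    zero_cols <- c("feeding_time_s", "dry_mass_g", "energy_kj", "ap_g",
                   "fat_g", "tnc_g", "ndf_g", "adf_g", "lignin_g")
    out[zero_cols] <- 0
    return(out)
  }
  key <- unique(bouts[, c("focal_id", "date")])
  if (nrow(key) != 1) {
    abort("daily_intake() expects bouts from a single focal-day.")
  }
  compute_daily_intakes(bouts, rates, handling, compositions, body_mass,
                        constants)
}
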