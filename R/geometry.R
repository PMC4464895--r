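#' Right-angled mixture triangle coordinates
#'
#' Expresses the contributions of available protein, fat and carbohydrate
#' (TNC) to fiber-free macronutrient energy as percentages. Protein is plotted
#' on the x-axis, fat on the y-axis, and carbohydrate on the implicit z-axis
#' (`z = 100 - x - y`).
#'
#' @param ap_kj,fat_kj,tnc_kj daily energy from each macronutrient, kJ (any
#'   common unit; only proportions matter).
#' @return A tibble with columns `x_protein`, `y_fat`, `z_carb` summing to
#'   100.
#' @export
#' @examples
#' rmt_coords(100, 200, 700)
rmt_coords <- function(ap_kj, fat_kj, tnc_kj) {
  if (any(ap_kj < 0) || any(fat_kj < 0) || any(tnc_kj < 0)) {
    abort("Energy inputs must be nonnegative.")
  }
  total <- ap_kj + fat_kj + tnc_kj
  if (any(total == 0)) {
    abort("Total macronutrient energy must be positive.")
  }
  tibble::tibble(
    x_protein = 100 * ap_kj / total,
    y_fat = 100 * fat_kj / total,
    z_carb = 100 * tnc_kj / total
  )
}

#' Carbohydrate isoline on a right-angled mixture triangle
#'
#' Points with a fixed percentage z of carbohydrate lie on the line
#' `x + y = 100 - z`, clipped to the first quadrant.
#'
#' @param z_percent carbohydrate percentage (0-100).
#' @return A tibble with the segment endpoints (`x`, `y`).
#' @export
#' @examples
#' carb_isoline(80)
carb_isoline <- function(z_percent) {
  if (z_percent < 0 || z_percent > 100) abort("`z_percent` must be in [0, 100].")
  s <- 100 - z_percent
  tibble::tibble(x = c(s, 0), y = c(0, s), z_carb = z_percent)
}

#' Convert between a protein energy proportion and the AP:NPE ratio
#'
#' If a fraction p of total macronutrient energy comes from available
#' protein, the ratio of protein to non-protein energy is `p / (1 - p)`;
#' `ratio_to_proportion()` is the exact inverse, `r / (1 + r)`.
#'
#' @param p fraction of energy from protein, in [0, 1).
#' @return The AP:NPE ratio.
#' @export
#' @examples
#' proportion_to_ratio(0.0947)
proportion_to_ratio <- function(p) {
  if (any(p < 0) || any(p >= 1)) abort("`p` must lie in [0, 1).")
  p / (1 - p)
}

#' @rdname proportion_to_ratio
#' @param r AP:NPE ratio (nonnegative).
#' @export
ratio_to_proportion <- function(r) {
  if (any(r < 0)) abort("`r` must be nonnegative.")
  r / (1 + r)
}

#' Fit a nutritional rail (regression through the origin)
#'
#' A population balancing its diet at a fixed protein to non-protein-energy
#' ratio places its daily (AP kJ, NPE kJ) intakes along a line through the
#' origin. The least-squares slope is `sum(ap * npe) / sum(ap^2)` (kJ NPE per
#' kJ AP) and its reciprocal is the implied AP:NPE ratio of the population.
#'
#' @param ap_kj,npe_kj daily (or season-group mean) intakes of
#'   available-protein and non-protein energy, kJ.
#' @return An object of class `rail_fit`: a list with `slope`,
#'   `implied_ap_npe`, `n_points` and `residual_cv` (coefficient of variation
#'   of perpendicular deviations from the rail, in % of the mean distance of
#'   points from the origin).
#' @export
#' @examples
#' fit_rail(c(1, 2), c(5, 10))
fit_rail <- function(ap_kj, npe_kj) {
  ok <- is.finite(ap_kj) & is.finite(npe_kj)
  ap_kj <- ap_kj[ok]
  npe_kj <- npe_kj[ok]
  if (length(ap_kj) < 2) abort("At least two points are needed to fit a rail.")
  if (any(ap_kj < 0) || any(npe_kj < 0)) {
    abort("Intakes must be nonnegative.")
  }
  if (all(ap_kj == 0)) abort("Degenerate rail: all AP intakes are zero.")
  slope <- sum(ap_kj * npe_kj) / sum(ap_kj^2)
  # perpendicular distance of each point from the rail y = slope * x
  perp <- (npe_kj - slope * ap_kj) / sqrt(1 + slope^2)
  origin_dist <- sqrt(ap_kj^2 + npe_kj^2)
  residual_cv <- if (mean(origin_dist) > 0) {
    100 * sd(perp) / mean(origin_dist)
  } else {
    NA_real_
  }
  structure(
    list(slope = slope,
         implied_ap_npe = 1 / slope,
         n_points = length(ap_kj),
         residual_cv = residual_cv),
    class = "rail_fit"
  )
}

#' @export
print.rail_fit <- function(x, ...) {
  cat("Nutritional rail (regression through the origin)\n")
  cat(sprintf("  points: %d\n", x$n_points))
  cat(sprintf("  slope (kJ NPE per kJ AP): %.4g\n", x$slope))
  cat(sprintf("  implied AP:NPE ratio: %.4g\n", x$implied_ap_npe))
  cat(sprintf("  residual spread (%% of mean origin distance): %.3g\n",
              x$residual_cv))
  invisible(x)
}

#' Coefficient of variation
#'
#' @param values numeric vector (n >= 2, nonzero mean).
#' @return 100 * sample standard deviation / mean, in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4))
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("Need at least two values.")
  m <- mean(values)
  if (m == 0) abort("Coefficient of variation is undefined for zero mean.")
  100 * sd(values) / m
}

#' Requirement threshold lines for the AP-NPE plane
#'
#' Converts mass-specific requirements to kJ/day lines in bivariate
#' (AP kJ, NPE kJ) intake space: a vertical line at the minimum protein
#' requirement and an oblique line of constant total energy
#' (`AP + NPE = energy_min`).
#'
#' @param protein_g_per_kg minimum protein requirement, g per kg body mass
#'   per day.
#' @param energy_per_mbm minimum energy requirement, kJ per kg^exponent per
#'   day.
#' @param mass_kg body mass, kg.
#' @param constants a [fuel_constants()] list.
#' @return A list with `protein_min_kj` (vertical line position) and
#'   `energy_min_kj` (intercept of the oblique line `npe = energy_min - ap`).
#' @export
#' @examples
#' threshold_lines(2.8, 500, 5)
threshold_lines <- function(protein_g_per_kg, energy_per_mbm, mass_kg,
                            constants = fuel_constants()) {
  if (protein_g_per_kg <= 0 || energy_per_mbm <= 0 || mass_kg <= 0) {
    abort("Thresholds and body mass must be positive.")
  }
  list(
    protein_min_kj = protein_requirement_kj(protein_g_per_kg, mass_kg,
                                            constants),
    energy_min_kj = energy_per_mbm * mass_kg^constants$metabolic_exponent
  )
}

#' Per-day mixture-triangle coordinates and macronutrient energies
#'
#' Converts a daily-intake table to per-day macronutrient energies (kJ),
#' right-angled mixture triangle coordinates (fiber excluded) and NPE
#' (fiber included), ready for geometry plots and summaries.
#'
#' @param daily a daily-intake tibble from [compute_daily_intakes()].
#' @param constants a [fuel_constants()] list.
#' @return `daily` with columns `ap_kj`, `fat_kj`, `tnc_kj`, `npe_kj`,
#'   `x_protein`, `y_fat`, `z_carb` appended.
#' @export
daily_geometry <- function(daily, constants = fuel_constants()) {
  daily <- tibble::as_tibble(daily)
  daily$ap_kj <- daily$ap_g * constants$kj_protein
  daily$fat_kj <- daily$fat_g * constants$kj_fat
  daily$tnc_kj <- daily$tnc_g * constants$kj_tnc
  fiber_kj <- constants$dig_cell * (daily$adf_g - daily$lignin_g) *
    constants$kj_fiber +
    constants$dig_hc * (daily$ndf_g - daily$adf_g) * constants$kj_fiber
  daily$npe_kj <- daily$tnc_kj + daily$fat_kj + fiber_kj
  total <- daily$ap_kj + daily$fat_kj + daily$tnc_kj
  coords <- tibble::tibble(x_protein = rep(NA_real_, nrow(daily)),
                           y_fat = NA_real_, z_carb = NA_real_)
  pos <- which(total > 0)
  if (length(pos)) {
    coords[pos, ] <- rmt_coords(daily$ap_kj[pos], daily$fat_kj[pos],
                                daily$tnc_kj[pos])
  }
  dplyr::bind_cols(daily, coords)
}
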