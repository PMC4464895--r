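#' Right-angled mixture triangle plot
#'
#' Scatter of daily diets in (protein %, fat %) space with the carbohydrate
#' percentage on the implicit axis, plus dotted carbohydrate isolines.
#'
#' @param geom a tibble with `x_protein`, `y_fat` columns (see
#'   [daily_geometry()]); a `season` column, if present, drives the colour
#'   scale and a `group_id` column the facets.
#' @param isolines carbohydrate percentages to draw as isolines.
#' @return A ggplot object.
#' @export
plot_rmt <- function(geom, isolines = c(60, 80)) {
  iso <- dplyr::bind_rows(lapply(isolines, carb_isoline))
  p <- ggplot2::ggplot(geom, ggplot2::aes(x = .data$x_protein,
                                          y = .data$y_fat)) +
    ggplot2::geom_line(
      data = iso,
      ggplot2::aes(x = .data$x, y = .data$y,
                   group = .data$z_carb),
      linetype = "dotted", colour = "grey40", inherit.aes = FALSE
    )
  if ("season" %in% names(geom)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$season)),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "Season")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  if ("group_id" %in% names(geom)) {
    p <- p + ggplot2::facet_wrap(~group_id)
  }
  p + ggplot2::labs(
    x = "Protein (% of macronutrient kJ)",
    y = "Fat (% of macronutrient kJ)",
    title = "Right-angled mixture triangle (carbohydrate on implicit axis)"
  ) +
    ggplot2::theme_minimal()
}

#' Protein vs non-protein energy plot with nutritional rail
#'
#' Bivariate plot of available-protein energy against non-protein energy
#' (kJ/day), with each group's through-origin rail and, optionally, the
#' requirement-threshold region (left of the minimum-protein vertical line
#' and/or below the minimum-energy oblique line).
#'
#' @param geom a tibble with `ap_kj` and `npe_kj` columns (see
#'   [daily_geometry()]); a `group_id` column, if present, gives one rail per
#'   group.
#' @param thresholds optional output of [threshold_lines()].
#' @return A ggplot object.
#' @export
plot_rail <- function(geom, thresholds = NULL) {
  geom <- dplyr::filter(geom, is.finite(.data$ap_kj), is.finite(.data$npe_kj))
  if ("group_id" %in% names(geom)) {
    rails <- geom |>
      dplyr::group_by(.data$group_id) |>
      dplyr::group_modify(~ tibble::tibble(
        slope = fit_rail(.x$ap_kj, .x$npe_kj)$slope
      )) |>
      dplyr::ungroup()
  } else {
    rails <- tibble::tibble(slope = fit_rail(geom$ap_kj, geom$npe_kj)$slope)
  }
  p <- ggplot2::ggplot(geom, ggplot2::aes(x = .data$ap_kj, y = .data$npe_kj))
  if (!is.null(thresholds)) {
    xmax <- max(geom$ap_kj) * 1.05
    ymax <- max(geom$npe_kj) * 1.05
    shade <- tibble::tibble(
      x = c(0, thresholds$protein_min_kj, thresholds$protein_min_kj,
            thresholds$energy_min_kj, xmax, xmax, 0),
      y = c(ymax, ymax, thresholds$energy_min_kj - thresholds$protein_min_kj,
            0, 0, 0, 0)
    )
    shade$y <- pmax(shade$y, 0)
    p <- p + ggplot2::geom_polygon(data = shade,
                                   ggplot2::aes(x = .data$x, y = .data$y),
                                   fill = "grey85", inherit.aes = FALSE) +
      ggplot2::geom_vline(xintercept = thresholds$protein_min_kj,
                          linetype = "dashed") +
      ggplot2::geom_abline(intercept = thresholds$energy_min_kj, slope = -1,
                           linetype = "dashed")
  }
  if ("group_id" %in% names(geom)) {
    p <- p + ggplot2::geom_abline(
      data = rails,
      ggplot2::aes(slope = .data$slope, intercept = 0),
      colour = "grey30"
    ) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_wrap(~group_id)
  } else {
    p <- p + ggplot2::geom_abline(slope = rails$slope[1], intercept = 0,
                                  colour = "grey30") +
      ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(
    x = "Available protein (kJ/day)",
    y = "Non-protein energy (kJ/day)",
    title = "Nutritional rail (regression through the origin)"
  ) +
    ggplot2::theme_minimal()
}
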