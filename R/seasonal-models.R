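period_mean_vars <- function() {
  c("feeding_time_s", "dry_mass_g", "frac_mass_fruit_seed", "energy_kj",
    "ap_g", "fat_g", "tnc_g", "ndf_g", "adf_g", "lignin_g", "ap_npe")
}

#' Aggregate daily intakes to individual-by-period means
#'
#' Daily values are averaged within each (focal, collection period) cell,
#' giving a more balanced data structure for mixed modelling (each cell is
#' typically based on 1-5 observation days). The matrix fill (individuals x
#' periods and the number of populated cells) is attached as attribute
#' `"fill"`.
#'
#' @param daily a daily-intake tibble from [compute_daily_intakes()].
#' @return A tibble with one row per populated (focal_id, period) cell:
#'   `focal_id`, `group_id`, `period`, `season`, `n_days` and the mean of
#'   each intake variable.
#' @export
build_period_table <- function(daily) {
  daily <- tibble::as_tibble(daily)
  if (nrow(daily) == 0) {
    out <- tibble::tibble(focal_id = character(), group_id = character(),
                          period = integer(), season = integer(),
                          n_days = integer())
    attr(out, "fill") <- list(n_individuals = 0L, n_periods = 0L,
                              populated_cells = 0L, total_cells = 0L)
    return(out)
  }
  vars <- intersect(period_mean_vars(), names(daily))
  out <- daily |>
    dplyr::group_by(.data$focal_id, .data$group_id, .data$period) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      dplyr::across(dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(season = assign_season(.data$period)) |>
    dplyr::arrange(.data$group_id, .data$focal_id, .data$period)
  n_ind <- dplyr::n_distinct(out$focal_id)
  n_per <- dplyr::n_distinct(out$period)
  attr(out, "fill") <- list(
    n_individuals = n_ind,
    n_periods = n_per,
    populated_cells = nrow(out),
    total_cells = n_ind * n_per
  )
  out
}

#' Variance-stabilising transformations for intake variables
#'
#' `arcsine_sqrt` (`asin(sqrt(p))`) stabilises proportions in [0, 1];
#' `log` is the natural logarithm for strictly positive skewed intakes;
#' `none` is the identity. `inverse_transform()` maps model-scale values
#' (e.g. estimated marginal means) back to the raw scale.
#'
#' @param values numeric vector.
#' @param transform one of `"none"`, `"arcsine_sqrt"`, `"log"`.
#' @return Transformed (or back-transformed) values.
#' @export
#' @examples
#' apply_transform(c(0, 0.5, 1), "arcsine_sqrt")
apply_transform <- function(values, transform = c("none", "arcsine_sqrt",
                                                  "log")) {
  transform <- match.arg(transform)
  switch(transform,
    none = values,
    arcsine_sqrt = {
      if (any(values < 0 | values > 1, na.rm = TRUE)) {
        abort("arcsine_sqrt requires proportions in [0, 1].")
      }
      asin(sqrt(values))
    },
    log = {
      if (any(values <= 0, na.rm = TRUE)) {
        abort("log transform requires strictly positive values.")
      }
      log(values)
    }
  )
}

#' @rdname apply_transform
#' @export
inverse_transform <- function(values, transform = c("none", "arcsine_sqrt",
                                                    "log")) {
  transform <- match.arg(transform)
  switch(transform,
    none = values,
    arcsine_sqrt = sin(values)^2,
    log = exp(values)
  )
}

#' Group-by-period linear mixed model for an intake variable
#'
#' Fits the repeated-measures model used for the individual-by-period table:
#' fixed effects of group, collection period (categorical) and their
#' interaction, and a random intercept per individual; fitting is delegated
#' to a standard REML routine. Returns Type III F tests for the fixed
#' effects, estimated marginal means per group (averaged over periods and
#' back-transformed to the raw scale when a transformation was applied), and
#' compact letter groupings from unadjusted (LSD) pairwise comparisons at
#' alpha = 0.05.
#'
#' @param table an individual-by-period table from [build_period_table()].
#' @param response name of the response column.
#' @param transform transformation applied before fitting (see
#'   [apply_transform()]).
#' @param method `"lmer"` (default; homoscedastic residuals, Satterthwaite
#'   denominator df, tolerates inestimable group x period cells) or `"lme"`
#'   (per-period residual variances via `nlme::varIdent`; requires a
#'   fully estimable fixed-effects design).
#' @return An object of class `group_period_lmm`: a list with elements
#'   `fixed_effects` (effect, F, df, p), `emmeans` (group, model-scale mean,
#'   SE, raw-scale mean, letter grouping), `transform`, `method`,
#'   `converged`, and the underlying fitted `model`.
#' @export
fit_group_period_model <- function(table, response,
                                   transform = c("none", "arcsine_sqrt",
                                                 "log"),
                                   method = c("lmer", "lme")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  table <- tibble::as_tibble(table)
  if (!response %in% names(table)) {
    abort(paste0("Response '", response, "' is not a column of the table."))
  }
  d <- tibble::tibble(
    y = apply_transform(table[[response]], transform),
    group = factor(table$group_id),
    period = factor(table$period),
    individual = factor(table$focal_id)
  )
  d <- d[is.finite(d$y), ]
  if (nlevels(droplevels(d$group)) < 2) {
    abort("At least two groups are required.")
  }
  if (nlevels(droplevels(d$period)) < 2) {
    abort("At least two periods are required.")
  }
  messages <- character()
  if (method == "lmer") {
    fit <- withCallingHandlers(
      lmerTest::lmer(y ~ group * period + (1 | individual), data = d,
                     REML = TRUE),
      message = function(m) {
        messages <<- c(messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    conv <- fit@optinfo$conv$lme4$messages
    converged <- is.null(conv)
    atab <- suppressMessages(anova(fit, type = 3))
    fixed <- tibble::tibble(
      effect = rownames(atab),
      F = atab$`F value`,
      df_num = atab$NumDF,
      df_den = atab$DenDF,
      p = atab$`Pr(>F)`
    )
  } else {
    fit <- nlme::lme(y ~ group * period, random = ~ 1 | individual,
                     weights = nlme::varIdent(form = ~ 1 | period),
                     data = d, method = "REML")
    converged <- TRUE
    atab <- anova(fit, type = "marginal")
    atab <- atab[rownames(atab) != "(Intercept)", ]
    fixed <- tibble::tibble(
      effect = rownames(atab),
      F = atab$`F-value`,
      df_num = atab$numDF,
      df_den = atab$denDF,
      p = atab$`p-value`
    )
  }
  emm <- suppressMessages(emmeans::emmeans(fit, "group"))
  emm_df <- as.data.frame(emm)
  pairs_df <- as.data.frame(
    suppressMessages(emmeans::contrast(emm, method = "pairwise",
                                       adjust = "none"))
  )
  groups_chr <- as.character(emm_df$group)
  sig <- matrix(FALSE, length(groups_chr), length(groups_chr),
                dimnames = list(groups_chr, groups_chr))
  pair_names <- strsplit(as.character(pairs_df$contrast), " - ", fixed = TRUE)
  for (k in seq_along(pair_names)) {
    a <- pair_names[[k]][1]
    b <- pair_names[[k]][2]
    s <- is.finite(pairs_df$p.value[k]) && pairs_df$p.value[k] < 0.05
    sig[a, b] <- sig[b, a] <- s
  }
  emm_tab <- tibble::tibble(
    group = groups_chr,
    emmean = emm_df$emmean,
    se = emm_df$SE,
    emmean_raw = inverse_transform(emm_df$emmean, transform),
    letters = lsd_letters(groups_chr, sig)
  ) |>
    dplyr::arrange(.data$group)
  emm_tab$letters[!is.finite(emm_tab$emmean)] <- NA_character_
  structure(
    list(response = response,
         fixed_effects = fixed,
         emmeans = emm_tab,
         transform = transform,
         method = method,
         converged = converged,
         messages = messages,
         model = fit),
    class = "group_period_lmm"
  )
}

#' @export
print.group_period_lmm <- function(x, ...) {
  cat("Group x period linear mixed model for '", x$response, "'\n", sep = "")
  cat("  transform: ", x$transform, "; engine: ", x$method,
      if (!x$converged) " (DID NOT CONVERGE)" else "", "\n", sep = "")
  cat("  Fixed-effect F tests:\n")
  print(as.data.frame(x$fixed_effects), row.names = FALSE, digits = 4)
  cat("  Estimated marginal means (raw scale, LSD letter groups):\n")
  print(as.data.frame(x$emmeans[, c("group", "emmean_raw", "letters")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

# Compact letter display by insert-and-absorb: start from one set holding all
# groups; every significantly different pair splits the sets containing both;
# sets contained in another are absorbed; surviving sets get letters.
lsd_letters <- function(groups, sig) {
  sets <- list(groups)
  for (a in groups) {
    for (b in groups) {
      if (a < b && sig[a, b]) {
        new_sets <- list()
        for (s in sets) {
          if (a %in% s && b %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        keep <- rep(TRUE, length(new_sets))
        for (i in seq_along(new_sets)) {
          for (j in seq_along(new_sets)) {
            if (i != j && keep[j] &&
                all(new_sets[[i]] %in% new_sets[[j]]) &&
                (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
              keep[i] <- FALSE
              break
            }
          }
        }
        sets <- new_sets[keep]
      }
    }
  }
  sets <- sets[order(vapply(sets, function(s) match(s[1], groups), 1L))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  unname(out[groups])
}

mean_sd <- function(x) {
  x <- x[is.finite(x)]
  tibble::tibble(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
}

#' Descriptive group and seasonal summary tables
#'
#' Produces the three standard summaries of a daily-intake table: per-group
#' annual means of energy and available protein (raw and scaled to
#' (metabolic) body mass), group-by-season means of the scaled intakes, and
#' per-group macronutrient energy shares with the AP:NPE ratio and its
#' coefficient of variation. Shares and ratios are computed per focal-day
#' and then averaged (`shares_method = "daily_mean"`), or from summed daily
#' energies (`"ratio_of_sums"`).
#'
#' @param daily a daily-intake tibble from [compute_daily_intakes()].
#' @param constants a [fuel_constants()] list.
#' @param shares_method how group-level shares and ratios aggregate daily
#'   values.
#' @return A list of three tibbles: `group_summary`, `group_season_summary`,
#'   `macronutrient_shares` (each with a TOTAL row where applicable).
#' @export
descriptive_tables <- function(daily, constants = fuel_constants(),
                               shares_method = c("daily_mean",
                                                 "ratio_of_sums")) {
  shares_method <- match.arg(shares_method)
  daily <- tibble::as_tibble(daily)
  if (nrow(daily) == 0) abort("`daily` is empty.")
  geom <- daily_geometry(daily, constants)

  summarise_group <- function(d) {
    tibble::tibble(
      n_days = nrow(d),
      energy_kj_mean = mean(d$energy_kj),
      energy_kj_sd = sd(d$energy_kj),
      energy_per_mbm_mean = mean(d$energy_per_mbm),
      ap_g_mean = mean(d$ap_g),
      ap_g_sd = sd(d$ap_g),
      ap_per_bm_mean = mean(d$ap_per_bm)
    )
  }
  grp <- geom |>
    dplyr::group_by(group_id = .data$group_id) |>
    dplyr::group_modify(~ summarise_group(.x)) |>
    dplyr::ungroup()
  total <- dplyr::bind_cols(tibble::tibble(group_id = "TOTAL"),
                            summarise_group(geom))
  group_summary <- dplyr::bind_rows(grp, total)

  group_season_summary <- geom |>
    dplyr::group_by(.data$group_id, .data$season) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      energy_per_mbm_mean = mean(.data$energy_per_mbm),
      energy_per_mbm_sd = sd(.data$energy_per_mbm),
      ap_per_bm_mean = mean(.data$ap_per_bm),
      ap_per_bm_sd = sd(.data$ap_per_bm),
      .groups = "drop"
    )

  safe_cv <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2 || mean(x) == 0) NA_real_ else 100 * sd(x) / mean(x)
  }
  summarise_shares <- function(d) {
    if (shares_method == "daily_mean") {
      tibble::tibble(
        share_protein_mean = mean(d$x_protein, na.rm = TRUE),
        share_protein_sd = sd(d$x_protein[is.finite(d$x_protein)]),
        share_fat_mean = mean(d$y_fat, na.rm = TRUE),
        share_fat_sd = sd(d$y_fat[is.finite(d$y_fat)]),
        share_carb_mean = mean(d$z_carb, na.rm = TRUE),
        share_carb_sd = sd(d$z_carb[is.finite(d$z_carb)]),
        ap_npe_mean = mean(d$ap_npe, na.rm = TRUE),
        ap_npe_sd = sd(d$ap_npe[is.finite(d$ap_npe)]),
        ap_npe_cv = safe_cv(d$ap_npe)
      )
    } else {
      tot <- rmt_coords(sum(d$ap_kj), sum(d$fat_kj), sum(d$tnc_kj))
      tibble::tibble(
        share_protein_mean = tot$x_protein,
        share_protein_sd = NA_real_,
        share_fat_mean = tot$y_fat,
        share_fat_sd = NA_real_,
        share_carb_mean = tot$z_carb,
        share_carb_sd = NA_real_,
        ap_npe_mean = sum(d$ap_kj) / sum(d$npe_kj),
        ap_npe_sd = NA_real_,
        ap_npe_cv = safe_cv(d$ap_npe)
      )
    }
  }
  shr <- geom |>
    dplyr::group_by(group_id = .data$group_id) |>
    dplyr::group_modify(~ summarise_shares(.x)) |>
    dplyr::ungroup()
  shr_total <- dplyr::bind_cols(tibble::tibble(group_id = "TOTAL"),
                                summarise_shares(geom))
  macronutrient_shares <- dplyr::bind_rows(shr, shr_total)

  list(group_summary = group_summary,
       group_season_summary = group_season_summary,
       macronutrient_shares = macronutrient_shares)
}
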