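#' Configuration for a synthetic observational study
#'
#' Defines the generating conditions for [gen_study()]: a multi-group design
#' along a habitat-disturbance gradient (disturbance expressed as a basal-area
#' proxy in (0, 1], 1 = least disturbed), twelve collection periods mapped to
#' five seasons, seasonally varying frugivory and dry-mass intake, and a
#' common dietary AP:NPE target that food choice balances toward. Defaults
#' emulate a five-group, 18-individual sifaka study: lean-season mass intake
#' falls to `lean_intake_multiplier` (0.4) of the least-disturbed group's
#' abundant-season intake and converges across groups, abundant-season intake
#' scales with disturbance, and the dietary AP:NPE target is 0.105.
#'
#' @param seed integer seed driving all randomness.
#' @param group_ids group labels.
#' @param disturbance per-group basal-area proxy in (0, 1].
#' @param n_individuals per-group number of focal animals.
#' @param periods_sampled list of integer vectors: collection periods (1-12)
#'   in which each group was followed.
#' @param days_per_period scalar or length-2 range: focal-days per individual
#'   per period (drawn uniformly from the range).
#' @param n_foods number of foods in the generated library (>= 4).
#' @param lean_intake_multiplier lean-season dry-mass intake as a fraction of
#'   the undisturbed abundant-season intake, in (0, 1].
#' @param target_ap_npe dietary AP:NPE ratio food choice balances toward
#'   (recycled per group).
#' @param frugivory_abundant,frugivory_lean per-group fruit/seed fraction of
#'   ingested dry mass by season class.
#' @param base_mass_g abundant-season daily dry-mass intake (g) of an
#'   undisturbed-habitat animal.
#' @param disturbance_floor fraction of `base_mass_g` retained at
#'   disturbance 0 in the abundant season.
#' @param feeding_s_per_day calibration anchor: approximate feeding seconds
#'   per day for an undisturbed-habitat animal in the abundant season.
#' @param bouts_per_day Poisson mean number of feeding bouts per day.
#' @param bout_gamma_shape gamma shape for bout durations (> 0;
#'   overdispersion control).
#' @param mass_cv day-level coefficient of variation of ingested dry mass
#'   (lognormal, mean-preserving).
#' @param body_mass_mean_kg,body_mass_sd_kg individual body-mass
#'   distribution.
#' @param frac_unmeasured fraction of foods left chemically unassayed (their
#'   chemistry is filled by the substitution hierarchy downstream).
#' @param noise if `FALSE`, every stochastic day-level component is replaced
#'   by its expectation: the pipeline then reproduces the generator's truth
#'   table exactly.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         group_ids = c("CONT1", "CONT2", "FRAG2", "FRAG3",
                                       "FRAG4"),
                         disturbance = c(0.886, 1.0, 0.389, 0.210, 0.510),
                         n_individuals = c(5L, 4L, 3L, 3L, 3L),
                         periods_sampled = list(1:12, 1:12, 1:12, 1:2, 3:12),
                         days_per_period = c(1L, 5L),
                         n_foods = 20L,
                         lean_intake_multiplier = 0.4,
                         target_ap_npe = 0.105,
                         frugivory_abundant = c(0.70, 0.72, 0.50, 0.30,
                                                0.70),
                         frugivory_lean = c(0.35, 0.35, 0.22, 0.15, 0.35),
                         base_mass_g = 500,
                         disturbance_floor = 0.35,
                         feeding_s_per_day = 10800,
                         bouts_per_day = 48,
                         bout_gamma_shape = 2,
                         mass_cv = 0.3,
                         body_mass_mean_kg = 5,
                         body_mass_sd_kg = 0.4,
                         frac_unmeasured = 0,
                         noise = TRUE) {
  n_groups <- length(group_ids)
  cfg <- list(
    seed = as.integer(seed),
    group_ids = group_ids,
    n_groups = n_groups,
    disturbance = rep_len(disturbance, n_groups),
    n_individuals = rep_len(as.integer(n_individuals), n_groups),
    periods_sampled = rep_len(periods_sampled, n_groups),
    days_per_period = as.integer(days_per_period),
    n_foods = as.integer(n_foods),
    lean_intake_multiplier = lean_intake_multiplier,
    target_ap_npe = rep_len(target_ap_npe, n_groups),
    frugivory_abundant = rep_len(frugivory_abundant, n_groups),
    frugivory_lean = rep_len(frugivory_lean, n_groups),
    base_mass_g = base_mass_g,
    disturbance_floor = disturbance_floor,
    feeding_s_per_day = feeding_s_per_day,
    bouts_per_day = bouts_per_day,
    bout_gamma_shape = bout_gamma_shape,
    mass_cv = mass_cv,
    body_mass_mean_kg = body_mass_mean_kg,
    body_mass_sd_kg = body_mass_sd_kg,
    frac_unmeasured = frac_unmeasured,
    noise = isTRUE(noise)
  )
  if (any(cfg$disturbance <= 0) || any(cfg$disturbance > 1)) {
    abort("`disturbance` must lie in (0, 1].")
  }
  if (cfg$lean_intake_multiplier <= 0 || cfg$lean_intake_multiplier > 1) {
    abort("`lean_intake_multiplier` must lie in (0, 1].")
  }
  frug <- c(cfg$frugivory_abundant, cfg$frugivory_lean)
  if (any(frug <= 0) || any(frug >= 1)) {
    abort("Frugivory fractions must lie in (0, 1).")
  }
  if (cfg$n_foods < 4) abort("`n_foods` must be at least 4.")
  if (any(vapply(cfg$periods_sampled,
                 function(p) any(!p %in% 1:12), logical(1)))) {
    abort("`periods_sampled` entries must be subsets of 1..12.")
  }
  if (length(cfg$days_per_period) == 1) {
    cfg$days_per_period <- rep(cfg$days_per_period, 2)
  }
  structure(cfg, class = "study_config")
}

#' Generate a synthetic food-composition library
#'
#' Draws leaf-like foods (young leaves, shoots, flowers, buds: moderate
#' protein, low fat, fibrous) and fruit/seed-like foods (low protein, higher
#' fat and TNC), with concentration spans matching wild-food chemistry
#' (available protein 0-13%, TNC 20-57%, fat 0-25%, NDF 28-55% of dry
#' matter). One unripe fruit is given zero available protein
#' (ADICP = CP). Mass closure holds by construction (ash and TNC absorb the
#' remainder) and `ndf >= adf >= lignin` always.
#'
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param n_foods number of foods (>= 4).
#' @return A measured composition tibble (see [validate_composition()]).
#' @export
gen_food_library <- function(seed = 1, n_foods = 20L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n_foods < 4) abort("`n_foods` must be at least 4.")
  n_leaf <- ceiling(n_foods / 2)
  n_fruit <- n_foods - n_leaf
  leaf_parts <- rep_len(c("YL", "YL", "SH", "BD", "FL", "YL"), n_leaf)
  fruit_parts <- rep_len(c("F", "FSD", "SD", "URFSD"), n_fruit)
  genera <- paste0("Genus", rep_len(1:8, n_foods))
  species <- paste0("species", seq_len(n_foods))
  part <- c(leaf_parts, fruit_parts)
  is_leaf <- seq_len(n_foods) <= n_leaf
  cp <- ifelse(is_leaf, runif(n_foods, 6, 16), runif(n_foods, 2, 14))
  adicp <- cp * runif(n_foods, 0.1, 0.3)
  fat <- ifelse(is_leaf, runif(n_foods, 0.5, 7), runif(n_foods, 1, 25))
  ndf <- ifelse(is_leaf, runif(n_foods, 32, 55), runif(n_foods, 28, 46))
  adf <- ndf * runif(n_foods, 0.55, 0.75)
  lignin <- adf * runif(n_foods, 0.30, 0.50)
  ash <- runif(n_foods, 2, 7)
  # first unripe fruit: protein fully fiber-bound, AP = 0
  zero_ap <- which(part == "URFSD")[1]
  if (!is.na(zero_ap)) adicp[zero_ap] <- cp[zero_ap]
  tnc_check <- 100 - (fat + (cp - adicp) + ash + ndf)
  stopifnot(all(tnc_check > 0))
  tibble::tibble(
    food_id = paste0(part, "_", species),
    species = species,
    genus = genera,
    part_code = part,
    cp = cp, adicp = adicp, fat = fat, ash = ash,
    ndf = ndf, adf = adf, lignin = lignin,
    measured = TRUE
  )
}

# Mass-share weights over foods hitting a fruit/seed mass fraction phi and,
# as closely as attainable, a dietary AP:NPE target. Within each pool the
# uniform base weights are tilted exponentially along the foods' AP:NPE
# spectrum; the tilt is solved by root finding.
solve_diet_weights <- function(derived, phi, target_ratio) {
  is_fruit <- derived$part_code %in% fruit_seed_parts()
  if (!any(is_fruit) || !any(!is_fruit)) {
    abort("The library needs both fruit/seed and non-fruit foods.")
  }
  ap_kj <- derived$ap / 100 * 16.736
  npe_kj <- derived$energy_kj_per_g - ap_kj
  z <- as.numeric(scale(derived$ap_npe))
  weights_at <- function(t) {
    w <- exp(t * z)
    w[is_fruit] <- phi * w[is_fruit] / sum(w[is_fruit])
    w[!is_fruit] <- (1 - phi) * w[!is_fruit] / sum(w[!is_fruit])
    w
  }
  ratio_at <- function(t) {
    w <- weights_at(t)
    sum(w * ap_kj) / sum(w * npe_kj)
  }
  lo <- ratio_at(-30)
  hi <- ratio_at(30)
  if (target_ratio <= lo) {
    warn(sprintf("Dietary AP:NPE target %.3f below attainable range [%.3f, %.3f]; clamped.",
                 target_ratio, lo, hi))
    t <- -30
  } else if (target_ratio >= hi) {
    warn(sprintf("Dietary AP:NPE target %.3f above attainable range [%.3f, %.3f]; clamped.",
                 target_ratio, lo, hi))
    t <- 30
  } else {
    t <- uniroot(function(t) ratio_at(t) - target_ratio, c(-30, 30),
                 tol = 1e-12)$root
  }
  w <- weights_at(t)
  list(weights = w, achieved_ratio = ratio_at(t), tilt = t)
}

#' Generate a complete synthetic observational study
#'
#' Produces the full input set of the intake pipeline (feeding bouts, intake
#' rates, unit masses, body masses and a food-composition library) together
#' with a ground-truth table of the expected daily intakes every focal-day
#' was generated from. Daily bout counts are Poisson, durations gamma, and
#' food choice multinomial with group- and season-dependent weights chosen so
#' that (i) the fruit/seed mass fraction matches the configured frugivory,
#' (ii) the dietary AP:NPE matches the configured target in expectation, and
#' (iii) expected dry mass follows the group-by-season means (abundant-season
#' intake scales with the disturbance proxy; lean-season intake converges
#' across groups to `lean_intake_multiplier` times the undisturbed
#' abundant-season intake). With `noise = FALSE` the generated data are the
#' expectations themselves and the pipeline output equals `truth_daily`
#' exactly.
#'
#' @param config a [study_config()].
#' @return A list of class `synthetic_study` with elements `config`, `foods`
#'   (library as observed, possibly with unassayed rows), `resolved` (derived
#'   chemistry actually used), `bouts`, `rates`, `handling`, `body_mass`,
#'   `truth_daily` (expected per-focal-day intakes), `truth_group_season`
#'   (generating group-by-season means) and `weights` (diet weights per
#'   group and season class).
#' @export
gen_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  foods <- gen_food_library(seed = NULL, n_foods = config$n_foods)
  # optionally blank out chemistry for a fraction of foods (keeping at least
  # one measured food per affected part code so substitution can resolve)
  if (config$frac_unmeasured > 0) {
    n_blank <- floor(config$frac_unmeasured * nrow(foods))
    cand <- sample(nrow(foods))
    blanked <- integer()
    for (i in cand) {
      if (length(blanked) >= n_blank) break
      part <- foods$part_code[i]
      still <- setdiff(which(foods$part_code == part & foods$measured),
                       c(blanked, i))
      if (length(still) >= 1) blanked <- c(blanked, i)
    }
    foods[blanked, chemistry_cols()] <- NA_real_
    foods$measured[blanked] <- FALSE
  }
  resolved <- derive_composition(resolve_compositions(foods))

  is_leaf <- !resolved$part_code %in% fruit_seed_parts()
  rate_units <- ifelse(is_leaf, runif(nrow(resolved), 0.5, 2),
                       runif(nrow(resolved), 0.05, 0.3))
  unit_mass <- ifelse(is_leaf, runif(nrow(resolved), 0.05, 0.3),
                      runif(nrow(resolved), 0.5, 3))
  # calibrate unit masses so an undisturbed abundant-season diet yields
  # base_mass_g in feeding_s_per_day seconds
  ref_group <- which.max(config$disturbance)
  ref_w <- solve_diet_weights(resolved, config$frugivory_abundant[ref_group],
                              config$target_ap_npe[ref_group])$weights
  g_raw <- rate_units * unit_mass
  mass_rate_ref <- 1 / sum(ref_w / g_raw)
  unit_mass <- unit_mass *
    (config$base_mass_g / config$feeding_s_per_day) / mass_rate_ref

  rates <- tibble::tibble(
    food_id = resolved$food_id,
    mode = ifelse(is_leaf, "count_per_interval", "per_item_duration"),
    units = rate_units * 64,
    duration_s = 64
  )
  handling <- tibble::tibble(
    food_id = resolved$food_id,
    unit_mass_g = unit_mass,
    conversion_factor = 1
  )
  g_per_s <- rate_units * unit_mass * 1

  # diet weights and expected mass per group x season class
  weights <- list()
  for (g in seq_len(config$n_groups)) {
    for (cls in c("abundant", "lean")) {
      phi <- if (cls == "lean") config$frugivory_lean[g] else
        config$frugivory_abundant[g]
      sol <- solve_diet_weights(resolved, phi, config$target_ap_npe[g])
      weights[[paste(config$group_ids[g], cls, sep = ".")]] <- c(
        sol, list(phi = phi)
      )
    }
  }
  abundant_mass <- config$base_mass_g *
    (config$disturbance_floor +
       (1 - config$disturbance_floor) * config$disturbance)
  lean_mass <- rep(config$lean_intake_multiplier * config$base_mass_g,
                   config$n_groups)

  # individuals and body masses
  focal <- do.call(rbind, lapply(seq_len(config$n_groups), function(g) {
    data.frame(
      focal_id = sprintf("%s-i%d", config$group_ids[g],
                         seq_len(config$n_individuals[g])),
      group_id = config$group_ids[g]
    )
  }))
  mass_kg <- if (config$noise) {
    pmin(pmax(rnorm(nrow(focal), config$body_mass_mean_kg,
                    config$body_mass_sd_kg), 3.5), 6.5)
  } else {
    rep(config$body_mass_mean_kg, nrow(focal))
  }
  body_mass <- tibble::tibble(focal_id = focal$focal_id,
                              mass_kg = round(mass_kg, 3),
                              age_class = "adult")

  base_date <- as.Date("2006-06-16")
  sdlog <- sqrt(log(1 + config$mass_cv^2))
  shape <- config$bout_gamma_shape

  bout_rows <- list()
  truth_rows <- list()
  for (g in seq_len(config$n_groups)) {
    gid <- config$group_ids[g]
    inds <- focal$focal_id[focal$group_id == gid]
    for (p in config$periods_sampled[[g]]) {
      season <- assign_season(p)
      cls <- if (is_lean_season(season)) "lean" else "abundant"
      wsol <- weights[[paste(gid, cls, sep = ".")]]
      w <- wsol$weights
      m_mean <- if (cls == "lean") lean_mass[g] else abundant_mass[g]
      tau <- (w / g_per_s) / sum(w / g_per_s)
      mass_rate <- 1 / sum(w / g_per_s)
      for (ind in inds) {
        dp <- config$days_per_period
        nd <- if (config$noise && dp[1] != dp[2]) {
          sample(seq(dp[1], dp[2]), 1)
        } else {
          round(mean(dp))
        }
        for (d in seq_len(nd)) {
          date <- as.character(base_date + (p - 1) * 30 + d)
          m_day <- if (config$noise) {
            m_mean * exp(rnorm(1, -sdlog^2 / 2, sdlog))
          } else {
            m_mean
          }
          S <- m_day / mass_rate
          if (config$noise) {
            n_b <- max(1L, rpois(1, config$bouts_per_day))
            f_idx <- sample(seq_along(tau), n_b, replace = TRUE, prob = tau)
            durs <- rgamma(n_b, shape = shape, rate = shape / (S / n_b))
            durs <- pmax(durs, 1e-6)
          } else {
            f_idx <- which(tau > 1e-12)
            durs <- tau[f_idx] * S
          }
          bout_rows[[length(bout_rows) + 1L]] <- tibble::tibble(
            focal_id = ind, group_id = gid, date = date, period = p,
            food_id = resolved$food_id[f_idx], duration_s = durs,
            is_soil = FALSE
          )
          # analytic expectation given the day's drawn mass budget
          grams_f <- m_day * w
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            focal_id = ind, group_id = gid, date = date, period = p,
            season = season, lean = cls == "lean",
            feeding_time_s = S,
            dry_mass_g = m_day,
            frac_mass_fruit_seed = wsol$phi,
            energy_kj = sum(grams_f * resolved$energy_kj_per_g),
            ap_g = sum(grams_f * resolved$ap / 100),
            fat_g = sum(grams_f * resolved$fat / 100),
            tnc_g = sum(grams_f * resolved$tnc / 100),
            ndf_g = sum(grams_f * resolved$ndf / 100),
            adf_g = sum(grams_f * resolved$adf / 100),
            lignin_g = sum(grams_f * resolved$lignin / 100)
          )
        }
      }
    }
  }
  bouts <- dplyr::bind_rows(bout_rows)
  truth_daily <- dplyr::bind_rows(truth_rows)
  truth_daily$ap_npe <- daily_ap_npe(truth_daily$ap_g, truth_daily$fat_g,
                                     truth_daily$tnc_g, truth_daily$ndf_g,
                                     truth_daily$adf_g, truth_daily$lignin_g)
  truth_daily <- dplyr::left_join(truth_daily,
                                  body_mass[, c("focal_id", "mass_kg")],
                                  by = "focal_id")
  truth_daily$energy_per_mbm <- scale_energy(truth_daily$energy_kj,
                                             truth_daily$mass_kg)
  truth_daily$ap_per_bm <- truth_daily$ap_g / truth_daily$mass_kg

  truth_group_season <- tidyr::expand_grid(
    g = seq_len(config$n_groups), season = 1:5
  ) |>
    dplyr::mutate(
      group_id = config$group_ids[.data$g],
      lean = is_lean_season(.data$season),
      expected_dry_mass_g = ifelse(.data$lean, lean_mass[.data$g],
                                   abundant_mass[.data$g]),
      target_ap_npe = config$target_ap_npe[.data$g],
      achieved_ap_npe = vapply(seq_len(dplyr::n()), function(i) {
        cls <- if (is_lean_season(season[i])) "lean" else "abundant"
        weights[[paste(group_id[i], cls, sep = ".")]]$achieved_ratio
      }, numeric(1)),
      frugivory = ifelse(.data$lean, config$frugivory_lean[.data$g],
                         config$frugivory_abundant[.data$g])
    ) |>
    dplyr::select(-"g")

  structure(
    list(config = config, foods = foods, resolved = resolved, bouts = bouts,
         rates = rates, handling = handling, body_mass = body_mass,
         truth_daily = truth_daily,
         truth_group_season = truth_group_season, weights = weights),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic focal-animal study\n")
  cat(sprintf("  %d groups, %d individuals, %d foods, %d focal-days, %d bouts\n",
              x$config$n_groups, sum(x$config$n_individuals),
              x$config$n_foods, nrow(x$truth_daily), nrow(x$bouts)))
  cat(sprintf("  noise: %s; seed: %d\n",
              if (x$config$noise) "on" else "off (expectation data)",
              x$config$seed))
  invisible(x)
}
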