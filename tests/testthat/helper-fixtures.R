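# Small hand-checkable fixtures and independent oracles used across tests.

toy_composition <- function() {
  tibble::tibble(
    food_id = c("YL_maesa", "YL_maesa2", "YL_unassayed", "FL_flower",
                "FL_unassayed", "FSD_fruit", "SD_seed"),
    species = c("maesa", "maesa2", "maesa3", "flower", "flower2", "fruit",
                "seed"),
    genus = c("Maesa", "Maesa", "Maesa", "Albizia", "Dombeya", "Syzygium",
              "Salacia"),
    part_code = c("YL", "YL", "YL", "FL", "FL", "FSD", "SD"),
    cp = c(14, 10, NA, 8, NA, 4, 5),
    adicp = c(2.5, 2, NA, 1, NA, 1, 0.8),
    fat = c(5.7, NA, NA, 3, NA, 2, 2),
    ash = c(5, 4, NA, 4, NA, 3, 3),
    ndf = c(29.5, 40, NA, 33, NA, 35, 43),
    adf = c(20, 28, NA, 20, NA, 22, 30),
    lignin = c(8, 12, NA, 7, NA, 9, 12),
    measured = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

# one food with round numbers: AP 8%, rate 0.5 units/s, 0.2 g/unit
toy_intake_inputs <- function() {
  comp <- tibble::tibble(
    food_id = "YL_toy", species = "toy", genus = "Toy", part_code = "YL",
    cp = 8, adicp = 0, fat = 2, ash = 5, ndf = 40, adf = 25, lignin = 10,
    measured = TRUE
  )
  list(
    comp = comp,
    rates = tibble::tibble(food_id = "YL_toy", mode = "count_per_interval",
                           units = 32, duration_s = 64),
    handling = tibble::tibble(food_id = "YL_toy", unit_mass_g = 0.2,
                              conversion_factor = 1)
  )
}

make_bout <- function(food_id, duration_s, focal = "f1", group = "g1",
                      date = "2006-07-01", period = 1L, is_soil = FALSE) {
  tibble::tibble(focal_id = focal, group_id = group, date = date,
                 period = period, food_id = food_id,
                 duration_s = duration_s, is_soil = is_soil)
}

# random valid measured compositions for property tests
random_compositions <- function(n, prefix = "rnd") {
  cp <- runif(n, 1, 18)
  adicp <- cp * runif(n, 0, 0.9)
  fat <- runif(n, 0, 15)
  ndf <- runif(n, 20, 55)
  adf <- ndf * runif(n, 0.4, 0.9)
  lignin <- adf * runif(n, 0.1, 0.6)
  ash <- runif(n, 1, 8)
  keep <- (fat + (cp - adicp) + ash + ndf) <= 100
  tibble::tibble(
    food_id = paste0(prefix, seq_len(n)),
    species = paste0("sp", seq_len(n)),
    genus = paste0("Gen", seq_len(n)),
    part_code = sample(part_codes(), n, replace = TRUE),
    cp = cp, adicp = adicp, fat = fat, ash = ash, ndf = ndf, adf = adf,
    lignin = lignin, measured = TRUE
  )[keep, ]
}

# Independent per-bout accumulation oracle: explicit loops and term-by-term
# fuel-value sums, no reliance on the package's vectorised path.
naive_daily_oracle <- function(bouts, rates, handling, comp) {
  comp <- as.data.frame(comp)
  rates <- as.data.frame(rates)
  handling <- as.data.frame(handling)
  bouts <- as.data.frame(bouts[!bouts$is_soil, ])
  keys <- unique(bouts[, c("focal_id", "date")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    b <- bouts[bouts$focal_id == keys$focal_id[k] &
                 bouts$date == keys$date[k], ]
    tot <- c(mass = 0, energy = 0, ap = 0, fat = 0, tnc = 0, ndf = 0,
             adf = 0, lignin = 0, fruit_mass = 0, time = 0)
    for (i in seq_len(nrow(b))) {
      fid <- b$food_id[i]
      r <- rates[rates$food_id == fid, ]
      rate <- sum(r$units) / sum(r$duration_s)
      h <- handling[handling$food_id == fid, ][1, ]
      cc <- comp[comp$food_id == fid, ][1, ]
      ap <- cc$cp - cc$adicp
      tnc <- 100 - (cc$fat + ap + cc$ash + cc$ndf)
      e <- ap / 100 * 16.736 + tnc / 100 * 16.736 + cc$fat / 100 * 37.656 +
        0.3911 * (cc$adf - cc$lignin) / 100 * 12.552 +
        0.5197 * (cc$ndf - cc$adf) / 100 * 12.552
      g <- b$duration_s[i] * rate * h$unit_mass_g * h$conversion_factor
      tot["mass"] <- tot["mass"] + g
      tot["energy"] <- tot["energy"] + g * e
      tot["ap"] <- tot["ap"] + g * ap / 100
      tot["fat"] <- tot["fat"] + g * cc$fat / 100
      tot["tnc"] <- tot["tnc"] + g * tnc / 100
      tot["ndf"] <- tot["ndf"] + g * cc$ndf / 100
      tot["adf"] <- tot["adf"] + g * cc$adf / 100
      tot["lignin"] <- tot["lignin"] + g * cc$lignin / 100
      tot["time"] <- tot["time"] + b$duration_s[i]
      if (cc$part_code %in% c("F", "FSD", "SD", "URFSD")) {
        tot["fruit_mass"] <- tot["fruit_mass"] + g
      }
    }
    out[[k]] <- c(focal_id = keys$focal_id[k], date = keys$date[k],
                  as.list(tot))
  }
  do.call(rbind.data.frame, out)
}

# direct LMM-stage simulation: balanced individual x period table with known
# group offsets, period effects, random individual intercepts and noise
simulate_period_table <- function(n_groups = 3, n_ind = 4, n_periods = 6,
                                  group_effect_sd = 0, period_effect_sd = 0,
                                  ind_sd = 0.5, resid_sd = 1, mu = 10) {
  groups <- paste0("G", seq_len(n_groups))
  g_eff <- if (group_effect_sd > 0) {
    scale(rnorm(n_groups))[, 1] * group_effect_sd
  } else {
    rep(0, n_groups)
  }
  p_eff <- if (period_effect_sd > 0) {
    scale(rnorm(n_periods))[, 1] * period_effect_sd
  } else {
    rep(0, n_periods)
  }
  rows <- list()
  for (g in seq_len(n_groups)) {
    for (i in seq_len(n_ind)) {
      fid <- paste0(groups[g], "-i", i)
      b <- rnorm(1, 0, ind_sd)
      for (p in seq_len(n_periods)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          focal_id = fid, group_id = groups[g], period = p,
          n_days = 1L,
          y = mu + g_eff[g] + p_eff[p] + b + rnorm(1, 0, resid_sd)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "group_effects") <- g_eff
  out
}
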