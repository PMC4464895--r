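test_that("intake rates pool as total units over total time", {
  expect_equal(pool_intake_rate(data.frame(units = c(10, 20),
                                           duration_s = c(60, 40))), 0.30)
  expect_equal(pool_intake_rate(data.frame(units = 6, duration_s = 60)),
               0.10)
  expect_error(pool_intake_rate(data.frame(units = numeric(),
                                           duration_s = numeric())),
               "No intake-rate records")
  pooled <- pool_intake_rates(tibble::tibble(
    food_id = c("a", "a", "b"), units = c(10, 20, 6),
    duration_s = c(60, 40, 60)
  ))
  expect_equal(pooled$rate_units_per_s[pooled$food_id == "a"], 0.30)
  expect_equal(pooled$rate_units_per_s[pooled$food_id == "b"], 0.10)
})

test_that("periods map to seasons and the lean flag", {
  expect_equal(assign_season(1:12), c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 5, 5))
  expect_true(is_lean_season(assign_season(1)))
  expect_false(is_lean_season(assign_season(7)))
  expect_equal(is_lean_season(1:5), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_error(assign_season(13), "1..12")
  expect_error(assign_season(0), "1..12")
})

test_that("a single bout multiplies out to mass, nutrients and energy", {
  inp <- toy_intake_inputs()
  bouts <- make_bout("YL_toy", 60)
  d <- daily_intake(bouts, inp$rates, inp$handling, inp$comp)
  # 60 s * 0.5 units/s * 0.2 g/unit = 6 g; AP 8% -> 0.48 g
  expect_equal(d$dry_mass_g, 6)
  expect_equal(d$ap_g, 0.48)
  e_food <- energy_density(ap = 8, tnc = 45, fat = 2, ndf = 40, adf = 25,
                           lignin = 10)
  expect_equal(d$energy_kj, 6 * e_food)
  expect_equal(d$feeding_time_s, 60)
  expect_equal(d$frac_mass_fruit_seed, 0)
})

test_that("an empty focal-day yields an all-zero record with missing AP:NPE", {
  inp <- toy_intake_inputs()
  d <- daily_intake(make_bout("YL_toy", 60)[0, ], inp$rates, inp$handling,
                    inp$comp, focal_id = "f1", group_id = "g1",
                    date = "2006-07-01", period = 3)
  expect_equal(d$dry_mass_g, 0)
  expect_equal(d$energy_kj, 0)
  expect_true(is.na(d$ap_npe))
  expect_equal(d$season, 2L)
})

test_that("daily intakes are additive over bout partitions", {
  inp <- toy_intake_inputs()
  one <- daily_intake(make_bout("YL_toy", 60), inp$rates, inp$handling,
                      inp$comp)
  two <- daily_intake(dplyr::bind_rows(make_bout("YL_toy", 30),
                                       make_bout("YL_toy", 30)),
                      inp$rates, inp$handling, inp$comp)
  for (v in c("dry_mass_g", "energy_kj", "ap_g", "ndf_g", "ap_npe")) {
    expect_equal(two[[v]], one[[v]], tolerance = 1e-12)
  }
})

test_that("longer bouts strictly increase mass and positive-concentration nutrients", {
  inp <- toy_intake_inputs()
  base <- daily_intake(make_bout("YL_toy", 60), inp$rates, inp$handling,
                       inp$comp)
  more <- daily_intake(make_bout("YL_toy", 61), inp$rates, inp$handling,
                       inp$comp)
  for (v in c("dry_mass_g", "energy_kj", "ap_g", "fat_g", "tnc_g",
              "ndf_g")) {
    expect_gt(more[[v]], base[[v]])
  }
})

test_that("doubling durations doubles amounts but not composition ratios", {
  set.seed(7)
  s <- gen_study(study_config(seed = 7, n_individuals = 1,
                              group_ids = "G1", disturbance = 1,
                              periods_sampled = list(1:2),
                              days_per_period = 1))
  doubled <- s$bouts
  doubled$duration_s <- doubled$duration_s * 2
  d1 <- suppressMessages(compute_daily_intakes(s$bouts, s$rates, s$handling,
                                               s$foods))
  d2 <- suppressMessages(compute_daily_intakes(doubled, s$rates, s$handling,
                                               s$foods))
  expect_equal(d2$dry_mass_g, 2 * d1$dry_mass_g, tolerance = 1e-12)
  expect_equal(d2$energy_kj, 2 * d1$energy_kj, tolerance = 1e-12)
  expect_equal(d2$ap_npe, d1$ap_npe, tolerance = 1e-12)
  expect_equal(d2$frac_mass_fruit_seed, d1$frac_mass_fruit_seed,
               tolerance = 1e-12)
})

test_that("day energy equals both the per-food and the per-nutrient decomposition", {
  set.seed(8)
  s <- gen_study(study_config(seed = 8, days_per_period = 1))
  d <- suppressMessages(compute_daily_intakes(s$bouts, s$rates, s$handling,
                                              s$foods, s$body_mass))
  const <- fuel_constants()
  fiber_kj <- const$dig_cell * (d$adf_g - d$lignin_g) * const$kj_fiber +
    const$dig_hc * (d$ndf_g - d$adf_g) * const$kj_fiber
  recomputed <- d$ap_g * const$kj_protein + d$tnc_g * const$kj_tnc +
    d$fat_g * const$kj_fat + fiber_kj
  expect_equal(d$energy_kj, recomputed, tolerance = 1e-9)
})

test_that("the vectorised engine matches the naive per-bout oracle", {
  set.seed(9)
  s <- gen_study(study_config(seed = 9, days_per_period = 1,
                              bouts_per_day = 12))
  d <- suppressMessages(compute_daily_intakes(s$bouts, s$rates, s$handling,
                                              s$foods))
  oracle <- naive_daily_oracle(s$bouts, s$rates, s$handling, s$resolved)
  m <- merge(as.data.frame(d), oracle, by = c("focal_id", "date"))
  expect_equal(nrow(m), nrow(d))
  expect_equal(m$dry_mass_g, m$mass, tolerance = 1e-9)
  expect_equal(m$energy_kj, m$energy, tolerance = 1e-9)
  expect_equal(m$ap_g, m$ap, tolerance = 1e-9)
  expect_equal(m$lignin_g, m$lignin, tolerance = 1e-9)
  expect_equal(m$frac_mass_fruit_seed, m$fruit_mass / m$mass,
               tolerance = 1e-9)
})

test_that("soil bouts are excluded from intakes but tallied in the audit", {
  inp <- toy_intake_inputs()
  bouts <- dplyr::bind_rows(
    make_bout("YL_toy", 60),
    make_bout("soil", 30, is_soil = TRUE)
  )
  d <- compute_daily_intakes(bouts, inp$rates, inp$handling, inp$comp)
  expect_equal(d$feeding_time_s, 60)
  expect_equal(d$dry_mass_g, 6)
  audit <- attr(d, "soil_audit")
  expect_equal(audit$soil_s, 30)
})

test_that("foods without intake rates inherit the part-code pooled rate", {
  comp <- dplyr::bind_rows(
    toy_intake_inputs()$comp,
    tibble::tibble(food_id = "YL_other", species = "other", genus = "Toy2",
                   part_code = "YL", cp = 10, adicp = 1, fat = 1, ash = 4,
                   ndf = 45, adf = 30, lignin = 12, measured = TRUE)
  )
  inp <- toy_intake_inputs()
  handling <- dplyr::bind_rows(
    inp$handling,
    tibble::tibble(food_id = "YL_other", unit_mass_g = 0.2,
                   conversion_factor = 1)
  )
  bouts <- make_bout("YL_other", 60)
  expect_message(
    d <- compute_daily_intakes(bouts, inp$rates, handling, comp),
    "substituted"
  )
  expect_equal(d$dry_mass_g, 6)  # inherits the 0.5 units/s YL pool
  # but a food whose part has no rates at all is an error
  comp2 <- comp
  comp2$part_code[comp2$food_id == "YL_other"] <- "SD"
  expect_error(
    suppressMessages(compute_daily_intakes(bouts, inp$rates, handling,
                                           comp2)),
    "no rates for part code"
  )
})

test_that("energy scales by metabolic body mass and protein requirements convert to kJ", {
  expect_equal(scale_energy(1673.6, 1), 1673.6)
  expect_equal(scale_energy(0, 5), 0)
  expect_equal(scale_energy(1704.5, 5), 1704.5 / 5^0.762)
  expect_error(scale_energy(100, 0), "positive")
  expect_equal(protein_requirement_kj(2.8, 5), 234)
  expect_equal(protein_requirement_kj(1.8, 5), 151)
  expect_equal(protein_requirement_kj(1, 1), 17)
  expect_error(protein_requirement_kj(-1, 5), "positive")
})

test_that("bout validation rejects bad durations and periods", {
  inp <- toy_intake_inputs()
  expect_error(compute_daily_intakes(make_bout("YL_toy", 0), inp$rates,
                                     inp$handling, inp$comp), "positive")
  expect_error(compute_daily_intakes(make_bout("YL_toy", 10, period = 13L),
                                     inp$rates, inp$handling, inp$comp),
               "1..12")
  expect_error(
    compute_daily_intakes(make_bout("YL_toy", 10), inp$rates,
                          inp$handling[0, ], inp$comp),
    "handling"
  )
})
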