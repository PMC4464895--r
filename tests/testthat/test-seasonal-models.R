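test_that("period aggregation averages days within individual-period cells", {
  inp <- toy_intake_inputs()
  bouts <- dplyr::bind_rows(
    make_bout("YL_toy", 60, date = "2006-07-01", period = 1L),
    make_bout("YL_toy", 120, date = "2006-07-02", period = 1L),
    make_bout("YL_toy", 90, date = "2006-08-20", period = 2L)
  )
  d <- compute_daily_intakes(bouts, inp$rates, inp$handling, inp$comp)
  pt <- build_period_table(d)
  expect_equal(nrow(pt), 2)
  expect_equal(pt$n_days, c(2L, 1L))
  expect_equal(pt$dry_mass_g, c(mean(c(6, 12)), 9))
  fill <- attr(pt, "fill")
  expect_equal(fill$populated_cells, 2L)
  expect_equal(fill$total_cells, 2L)
  expect_equal(nrow(build_period_table(d[0, ])), 0)
})

test_that("period aggregation is idempotent and order-independent", {
  set.seed(31)
  s <- gen_study(study_config(seed = 31, days_per_period = 2))
  d <- suppressMessages(compute_daily_intakes(s$bouts, s$rates, s$handling,
                                              s$foods, s$body_mass))
  pt1 <- build_period_table(d)
  pt2 <- build_period_table(d[sample(nrow(d)), ])
  expect_equal(pt1, pt2, ignore_attr = TRUE)
})

test_that("transformations and their inverses behave on their domains", {
  expect_equal(apply_transform(c(0, 1), "arcsine_sqrt"), c(0, pi / 2))
  expect_error(apply_transform(1.2, "arcsine_sqrt"), "\\[0, 1\\]")
  expect_error(apply_transform(0, "log"), "positive")
  x <- c(0.3, 1.7, 42)
  expect_equal(inverse_transform(apply_transform(x, "log"), "log"), x,
               tolerance = 1e-12)
  p <- seq(0, 1, by = 0.1)
  expect_equal(inverse_transform(apply_transform(p, "arcsine_sqrt"),
                                 "arcsine_sqrt"), p, tolerance = 1e-12)
  expect_identical(apply_transform(x, "none"), x)
})

test_that("group EMMs on balanced untransformed data equal cell-mean averages", {
  set.seed(32)
  tab <- simulate_period_table(n_groups = 3, n_ind = 4, n_periods = 4,
                               group_effect_sd = 2, period_effect_sd = 1)
  fit <- fit_group_period_model(tab, "y")
  cell_means <- tapply(tab$y, list(tab$group_id, tab$period), mean)
  expect_equal(fit$emmeans$emmean_raw, unname(rowMeans(cell_means)),
               tolerance = 1e-6)
  expect_equal(fit$emmeans$emmean, fit$emmeans$emmean_raw)
  expect_true(all(c("group", "period", "group:period") %in%
                    fit$fixed_effects$effect))
})

test_that("log-scale EMMs back-transform to the raw scale", {
  set.seed(33)
  tab <- simulate_period_table(n_groups = 2, n_ind = 4, n_periods = 3,
                               group_effect_sd = 0.3, mu = 3,
                               resid_sd = 0.2)
  tab$y <- exp(tab$y)
  fit <- fit_group_period_model(tab, "y", transform = "log")
  expect_equal(fit$emmeans$emmean_raw, exp(fit$emmeans$emmean))
  expect_true(all(fit$emmeans$emmean_raw > 0))
})

test_that("a strong simulated group effect is detected and ranked correctly", {
  set.seed(34)
  tab <- simulate_period_table(n_groups = 3, n_ind = 5, n_periods = 6,
                               group_effect_sd = 3, period_effect_sd = 0,
                               ind_sd = 0.3, resid_sd = 1)
  fit <- fit_group_period_model(tab, "y")
  p_group <- fit$fixed_effects$p[fit$fixed_effects$effect == "group"]
  expect_lt(p_group, 0.01)
  true_order <- order(attr(tab, "group_effects"))
  expect_equal(order(fit$emmeans$emmean), true_order)
  expect_true(fit$converged)
})

test_that("letter groupings separate significantly different groups only", {
  sig <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  expect_equal(nutrigeom:::lsd_letters(c("A", "B", "C"), sig),
               c("a", "a", "a"))
  sig["A", "C"] <- sig["C", "A"] <- TRUE
  lt <- nutrigeom:::lsd_letters(c("A", "B", "C"), sig)
  shared_ac <- intersect(strsplit(lt[1], "")[[1]], strsplit(lt[3], "")[[1]])
  expect_length(shared_ac, 0)
  expect_true(length(intersect(strsplit(lt[1], "")[[1]],
                               strsplit(lt[2], "")[[1]])) > 0)
  expect_true(length(intersect(strsplit(lt[2], "")[[1]],
                               strsplit(lt[3], "")[[1]])) > 0)
})

test_that("model preconditions require two groups and two periods", {
  set.seed(35)
  tab <- simulate_period_table(n_groups = 1, n_ind = 4, n_periods = 4)
  expect_error(fit_group_period_model(tab, "y"), "two groups")
  tab2 <- simulate_period_table(n_groups = 3, n_ind = 4, n_periods = 1)
  expect_error(fit_group_period_model(tab2, "y"), "two periods")
  tab3 <- simulate_period_table(n_groups = 2, n_ind = 3, n_periods = 3)
  expect_error(fit_group_period_model(tab3, "missing_col"), "missing_col")
})

test_that("heteroscedastic residual engine agrees on balanced designs", {
  set.seed(36)
  tab <- simulate_period_table(n_groups = 2, n_ind = 5, n_periods = 3,
                               group_effect_sd = 2)
  f1 <- fit_group_period_model(tab, "y", method = "lmer")
  f2 <- fit_group_period_model(tab, "y", method = "lme")
  expect_equal(f1$emmeans$emmean, f2$emmeans$emmean, tolerance = 1e-3)
})

test_that("descriptive tables summarise groups, seasons and shares", {
  set.seed(37)
  s <- gen_study(study_config(seed = 37, days_per_period = 2))
  d <- suppressMessages(compute_daily_intakes(s$bouts, s$rates, s$handling,
                                              s$foods, s$body_mass))
  tabs <- descriptive_tables(d)
  gs <- tabs$group_summary
  expect_equal(gs$group_id[nrow(gs)], "TOTAL")
  expect_equal(gs$n_days[nrow(gs)], nrow(d))
  expect_equal(sum(gs$n_days[-nrow(gs)]), nrow(d))
  # TOTAL mean is the day-weighted mean over groups
  byg <- gs[-nrow(gs), ]
  expect_equal(gs$energy_kj_mean[nrow(gs)],
               sum(byg$energy_kj_mean * byg$n_days) / sum(byg$n_days),
               tolerance = 1e-9)
  shares <- tabs$macronutrient_shares
  expect_equal(shares$share_protein_mean + shares$share_fat_mean +
                 shares$share_carb_mean, rep(100, nrow(shares)),
               tolerance = 1e-9)
  expect_true(all(tabs$group_season_summary$season %in% 1:5))
  # a constant-valued day set has zero SD
  one <- d[rep(1, 3), ]
  one$date <- paste0("d", 1:3)
  t1 <- descriptive_tables(one)
  expect_equal(t1$group_summary$energy_kj_sd, c(0, 0))
})
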