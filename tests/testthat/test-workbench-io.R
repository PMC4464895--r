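write_study_csvs <- function(s, dir) {
  paths <- list(
    comp = file.path(dir, "composition.csv"),
    bouts = file.path(dir, "bouts.csv"),
    rates = file.path(dir, "rates.csv"),
    handling = file.path(dir, "handling.csv"),
    bm = file.path(dir, "body_mass.csv")
  )
  readr::write_csv(s$foods, paths$comp)
  readr::write_csv(s$bouts, paths$bouts)
  readr::write_csv(s$rates, paths$rates)
  readr::write_csv(s$handling, paths$handling)
  readr::write_csv(s$body_mass, paths$bm)
  paths
}

test_that("composition CSVs round-trip with missing cells preserved", {
  dir <- withr::local_tempdir()
  lib <- toy_composition()
  path <- file.path(dir, "comp.csv")
  readr::write_csv(lib, path)
  back <- read_composition_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(lib))
  expect_true(is.na(back$fat[back$food_id == "YL_maesa2"]))
})

test_that("readers name the columns they are missing", {
  dir <- withr::local_tempdir()
  bad <- data.frame(food_id = "x", units = 1)
  path <- file.path(dir, "rates.csv")
  readr::write_csv(bad, path)
  expect_error(read_rates_csv(path), "duration_s")
  expect_error(read_rates_csv(file.path(dir, "nope.csv")), "nope.csv")
  b <- data.frame(focal_id = "f", date = "2006-07-01")
  readr::write_csv(b, file.path(dir, "bouts.csv"))
  expect_error(read_bouts_csv(file.path(dir, "bouts.csv")), "group_id")
})

test_that("external daily tables load through the schema-mapping layer", {
  dir <- withr::local_tempdir()
  ref <- reference_daily_intakes()
  renamed <- ref
  names(renamed)[names(renamed) == "energy_kj"] <- "Daily Energy (kJ)"
  path <- file.path(dir, "daily.csv")
  readr::write_csv(renamed, path)
  expect_error(suppressMessages(read_daily_intakes(path)), "energy_kj")
  loaded <- suppressMessages(
    read_daily_intakes(path, mapping = c(energy_kj = "Daily Energy (kJ)"))
  )
  expect_equal(nrow(loaded), nrow(ref))
  expect_equal(loaded$energy_kj, ref$energy_kj)
  expect_error(
    suppressMessages(read_daily_intakes(path, mapping = c(energy_kj = "no"))),
    "not found"
  )
  empty <- file.path(dir, "empty.csv")
  readr::write_csv(ref[0, ], empty)
  expect_error(suppressMessages(read_daily_intakes(empty)), "empty")
})

test_that("the pipeline runs end to end and writes every declared output", {
  dir <- withr::local_tempdir()
  s <- gen_study(study_config(seed = 51, days_per_period = 1))
  paths <- write_study_csvs(s, dir)
  cfg <- pipeline_config(paths$comp, paths$bouts, paths$rates,
                         paths$handling, paths$bm,
                         out_dir = file.path(dir, "out"))
  res <- suppressMessages(run_pipeline(cfg))
  for (f in c("composition_derived.csv", "daily_intakes.csv",
              "daily_geometry.csv", "rails.csv", "period_means.csv",
              "group_summary.csv", "group_season_summary.csv",
              "macronutrient_shares.csv", "provenance.json")) {
    expect_true(file.exists(file.path(dir, "out", f)), label = f)
  }
  expect_equal(nrow(res$daily), nrow(s$truth_daily))
  prov <- jsonlite::read_json(file.path(dir, "out", "provenance.json"))
  expect_equal(prov$n_focal_days, nrow(res$daily))
  expect_equal(prov$constants$kj_fat, 37.656)
})

test_that("re-running an identical configuration is byte-reproducible", {
  dir <- withr::local_tempdir()
  s <- gen_study(study_config(seed = 52, days_per_period = 1))
  paths <- write_study_csvs(s, dir)
  out1 <- file.path(dir, "out1")
  out2 <- file.path(dir, "out2")
  suppressMessages(run_pipeline(pipeline_config(
    paths$comp, paths$bouts, paths$rates, paths$handling, paths$bm,
    out_dir = out1)))
  suppressMessages(run_pipeline(pipeline_config(
    paths$comp, paths$bouts, paths$rates, paths$handling, paths$bm,
    out_dir = out2)))
  for (f in list.files(out1, pattern = "\\.csv$")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
})

test_that("missing input files abort with the offending path", {
  dir <- withr::local_tempdir()
  s <- gen_study(study_config(seed = 53, days_per_period = 1))
  paths <- write_study_csvs(s, dir)
  expect_error(
    pipeline_config(paths$comp, paths$bouts, file.path(dir, "no_rates.csv"),
                    paths$handling),
    "no_rates.csv"
  )
})

test_that("every output row is traceable to its input keys", {
  dir <- withr::local_tempdir()
  s <- gen_study(study_config(seed = 54, days_per_period = 1))
  paths <- write_study_csvs(s, dir)
  res <- suppressMessages(run_pipeline(pipeline_config(
    paths$comp, paths$bouts, paths$rates, paths$handling, paths$bm,
    out_dir = file.path(dir, "out"))))
  in_keys <- unique(paste(s$bouts$focal_id, s$bouts$date))
  out_keys <- paste(res$daily$focal_id, res$daily$date)
  expect_true(all(out_keys %in% in_keys))
  expect_true(all(res$derived$food_id %in% s$foods$food_id))
})
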