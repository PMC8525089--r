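test_that("identical seeds give identical systems", {
  cfg <- simulation_config(n_lakes = 3, years = 2015:2016, species_pool = 20,
                           n_env_lakes = 2, seed = 7)
  s1 <- generate_lake_system(cfg)
  s2 <- generate_lake_system(cfg)
  expect_identical(s1, s2)
  s3 <- generate_lake_system(simulation_config(n_lakes = 3, years = 2015:2016,
                                               species_pool = 20,
                                               n_env_lakes = 2, seed = 8))
  expect_false(identical(s1$surveys, s3$surveys))
})

test_that("seed is mandatory and an empty pool is rejected", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(species_pool = 0, seed = 1))
})

test_that("degenerate point niches confine species to their optimum class", {
  cfg <- simulation_config(n_lakes = 2, n_transects = 4, years = 2015,
                           species_pool = 10, n_env_lakes = 0,
                           optimum_mean = -1.5, optimum_sd = 0,
                           tolerance_meanlog = -20, tolerance_sdlog = 0,
                           max_presence_min = 0.9, max_presence_max = 0.9,
                           affinity_zero_prob = 0, affinity_min = 1,
                           affinity_max = 1, shoreline_frac = 0, seed = 3)
  sys <- generate_lake_system(cfg)
  expect_true(all(sys$surveys$depth_class == "1-2"))
  expect_true(all(sys$truth$expected_peak_depth == -1.5))
})

test_that("simulated mean alpha matches the closed-form expectation within 3 SE", {
  cfg <- simulation_config(n_lakes = 1, n_transects = 50, years = 2015,
                           species_pool = 20, n_env_lakes = 0,
                           optimum_mean = -3, optimum_sd = 0,
                           tolerance_meanlog = 0, tolerance_sdlog = 0,
                           max_presence_min = 0.8, max_presence_max = 0.8,
                           affinity_zero_prob = 0, affinity_min = 1,
                           affinity_max = 1, shoreline_frac = 0, seed = 21)
  sys <- generate_lake_system(cfg)
  a <- alpha_profile(sys$surveys)
  ea <- sys$truth$expected_alpha[1, ]
  # per-species Bernoulli(p): var of the per-transect count is sum p(1-p)
  p <- 0.8 * exp(-(depth_midpoints() + 3)^2 / 2)
  se <- sqrt(20 * p * (1 - p)) / sqrt(50)
  expect_true(all(abs(a - ea) <= 3 * se + 1e-12))
  expect_equal(depth_midpoints()[which.max(ea)], -3.0)
})

test_that("generated archives pass the selection rules untouched", {
  cfg <- simulation_config(n_lakes = 4, years = 2014:2016, species_pool = 30,
                           n_env_lakes = 0, seed = 5)
  sys <- generate_lake_system(cfg)
  f <- filter_records(sys$surveys, sys$lakes)
  log <- exclusion_log(f)
  expect_equal(sum(unlist(log)), 0)
  expect_equal(nrow(f), nrow(sys$surveys))
})

test_that("observed gamma dominates alpha at every depth in any configuration", {
  set.seed(9)
  for (i in 1:5) {
    cfg <- simulation_config(n_lakes = 2, n_transects = sample(2:5, 1),
                             years = 2015:2016, species_pool = sample(10:40, 1),
                             n_env_lakes = 0, seed = i)
    sys <- generate_lake_system(cfg)
    for (camp in split(sys$surveys, paste(sys$surveys$lake_id, sys$surveys$year))) {
      expect_true(all(gamma_profile(camp) >= alpha_profile(camp)))
    }
  }
})

test_that("monthly physiochemistry covers the twelve variables with flags and gaps", {
  cfg <- simulation_config(n_lakes = 3, n_env_lakes = 2, years = 2015:2016,
                           species_pool = 10, missing_month_prob = 0.2,
                           below_detection_prob = 0.3, seed = 13)
  sys <- generate_lake_system(cfg)
  m <- sys$monthly
  expect_setequal(unique(m$variable),
                  c("Chl", "Cond", "N_tot", "NH4", "NO3", "O2diss", "P_tot",
                    "pH", "SiO2", "Temp", "Transp", "SAC"))
  expect_setequal(unique(m$measure_depth[m$variable == "Temp"]), c(0, -2, -4, -6))
  expect_true(all(m$measure_depth[m$variable != "Temp"] == 0))
  expect_true(any(m$below_detection))
  # gaps: fewer than the full 15 series x 12 months per lake-year
  per_ly <- table(paste(m$lake_id, m$year))
  expect_true(all(per_ly < 15 * 12))
  expect_equal(length(unique(m$lake_id)), 2)
})

test_that("temporal generator validates years and records injected trend signs", {
  expect_error(generate_temporal_series(
    simulation_config(years = 2015:2016, seed = 1)), "3 years")
  cfg0 <- simulation_config(n_lakes = 2, years = 2014:2017, species_pool = 20,
                            n_env_lakes = 0, seed = 2)
  expect_equal(unname(generate_temporal_series(cfg0)$truth$trend_signs),
               c(0, 0))
  cfg1 <- simulation_config(n_lakes = 2, years = 2014:2017, species_pool = 20,
                            n_env_lakes = 0, optimum_drift_per_year = 0.5,
                            pool_drift_per_year = 2, seed = 2)
  tr <- generate_temporal_series(cfg1)$truth$trend_signs
  expect_equal(unname(tr["D_alpha_max"]), 1)
  expect_equal(unname(tr["total_gamma"]), 1)
})

test_that("a system writes to the canonical CSV schemas plus truth JSON", {
  cfg <- simulation_config(n_lakes = 2, years = 2015:2016, species_pool = 10,
                           n_env_lakes = 1, seed = 4)
  sys <- generate_lake_system(cfg)
  d <- withr::local_tempdir()
  write_lake_system(sys, d)
  expect_true(all(file.exists(file.path(d, c("surveys.csv", "lakes.csv",
                                             "waterlevel.csv", "monthly.csv",
                                             "truth.json")))))
  back <- read_surveys(file.path(d, "surveys.csv"))
  expect_equal(nrow(back), nrow(sys$surveys))
  expect_equal(nrow(read_monthly(file.path(d, "monthly.csv"))), nrow(sys$monthly))
})
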