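test_that("PET generator is deterministic and blockade-free conditions equal baseline", {
  cfg <- pet_sim_config(occupancy_truth = c(sham = 0, treat = 0),
                        noise_sd = 0.01, seed = 7)
  tacs1 <- gen_pet_study(cfg)
  tacs2 <- gen_pet_study(cfg)
  expect_identical(tacs1, tacs2)

  base <- tacs1[tacs1$condition == "baseline", ]
  for (cond in c("sham", "treat")) {
    tr <- tacs1[tacs1$condition == cond, ]
    expect_equal(tr$activity_kbq_ml, base$activity_kbq_ml)
  }
})

test_that("noiseless forward TAC matches a dense-grid convolution oracle", {
  regions <- data.frame(region = "roi", bp_nd = 2.0, r1 = 1.2, k2 = 0.1)
  cfg <- pet_sim_config(regions = regions, noise_sd = 0,
                        occupancy_truth = c(treat = 0.5))
  tacs <- gen_pet_study(cfg)
  tac <- get_tac(tacs, "roi", "baseline")
  tmid <- (tac$frame_start_min + tac$frame_end_min) / 2
  oracle <- oracle_srtm_tac(tmid, reference_tac, 1.2, 0.1, 2.0, dt = 0.01)
  expect_true(all(abs(tac$activity_kbq_ml - oracle) <=
                    0.001 * pmax(abs(oracle), 1e-6)))

  # treatment condition applies the fractional blockade to BP_ND
  tr <- get_tac(tacs, "roi", "treat")
  oracle_tr <- oracle_srtm_tac(tmid, reference_tac, 1.2, 0.1, 1.0, dt = 0.01)
  expect_true(all(abs(tr$activity_kbq_ml - oracle_tr) <=
                    0.001 * pmax(abs(oracle_tr), 1e-6)))
})

test_that("invalid frame schedules are rejected", {
  bad <- rbind(c(0, 2), c(1, 3))
  expect_error(pet_sim_config(frames = bad), "overlap")
  expect_error(pet_sim_config(frames = cbind(c(0, 2), c(0, 3))),
               "exceed")
  expect_error(pet_sim_config(occupancy_truth = c(x = 1.2)), "\\[0, 1\\]")
})

test_that("occupancy-series generator matches the closed forms when noiseless", {
  dose_cfg <- occupancy_series_config("dose", ed50 = 22.63,
                                      design_points = c(10, 30, 50, 100),
                                      noise_sd = 0)
  obs <- gen_occupancy_series(dose_cfg)
  expect_equal(obs$occupancy_pct,
               100 * obs$point / (22.63 + obs$point))
  # dose 30 with ED50 22.63 sits at 57% occupancy
  expect_equal(obs$occupancy_pct[obs$point == 30], 57, tolerance = 1e-3)

  day_cfg <- occupancy_series_config("day", occ_day0 = 78,
                                     lambda = log(78 / 48),
                                     design_points = 0:2, noise_sd = 0)
  day_obs <- gen_occupancy_series(day_cfg)
  expect_equal(day_obs$occupancy_pct[day_obs$point == 0], 78)
  expect_equal(day_obs$occupancy_pct[day_obs$point == 1], 48)

  # determinism and truncation with noise
  noisy_cfg <- occupancy_series_config("day", occ_day0 = 2,
                                       lambda = 1, design_points = 0:7,
                                       noise_sd = 10, replicates = 20,
                                       seed = 3)
  n1 <- gen_occupancy_series(noisy_cfg)
  expect_identical(n1, gen_occupancy_series(noisy_cfg))
  expect_true(all(n1$occupancy_pct >= 0 & n1$occupancy_pct <= 100))
})

test_that("occupancy-series config rejects mode/parameter mismatches", {
  expect_error(occupancy_series_config("dose", design_points = 1:3),
               "ed50")
  expect_error(occupancy_series_config("dose", ed50 = 10, occ_day0 = 50,
                                       lambda = 1, design_points = 1:3),
               "day-mode")
  expect_error(occupancy_series_config("day", occ_day0 = 120, lambda = 1,
                                       design_points = 0:3), "\\[0, 100\\]")
})
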