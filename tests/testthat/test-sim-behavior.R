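test_that("reward-size generator emits the task's reward sizes and is deterministic", {
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = "CON", a = 5, e = 0),
    trials_per_cell = 200, seed = 4)
  tr <- gen_reward_size_sessions(cfg)
  expect_setequal(unique(tr$reward_drops), c(1, 2, 4, 8))
  expect_identical(tr, gen_reward_size_sessions(cfg))
  expect_true(all(tr$outcome %in% c("correct", "early", "late")))
  # refused trials carry no RT; correct trials do
  expect_true(all(is.na(tr$rt_ms[tr$outcome != "correct"])))
  expect_true(all(!is.na(tr$rt_ms[tr$outcome == "correct"])))
})

test_that("very strong incentive drives refusals to zero", {
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = "CON", a = 1e6, e = 0),
    trials_per_cell = 500, seed = 9)
  tr <- gen_reward_size_sessions(cfg)
  expect_lt(mean(tr$outcome != "correct"), 0.001)
})

test_that("empirical cell means converge to configured probabilities at n = 1e5", {
  # E = 1/(a R) with a = 5.2 at R = 1: 0.1923 within ~3 binomial SEs
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = "CON", a = 5.2, e = 0),
    reward_sizes = 1, trials_per_cell = 1e5, seed = 21)
  tr <- gen_reward_size_sessions(cfg)
  p <- 1 / 5.2
  expect_lt(abs(mean(tr$outcome != "correct") - p), 0.004)

  cfg_wd <- behavior_sim_config("work_delay",
    conditions = data.frame(condition = "CON", k_w = 0.2, k_d = 0.2,
                            e0 = 0.05),
    cost_units = 2, trials_per_cell = 1e5, seed = 22)
  wd <- gen_work_delay_sessions(cfg_wd)
  del <- wd[wd$trial_type == "delay", ]
  expect_lt(abs(mean(del$outcome != "correct") - 0.45), 0.005)
})

test_that("flat cost truth yields refusal rates near E0 at every CU", {
  cfg <- behavior_sim_config("work_delay",
    conditions = data.frame(condition = "CON", k_w = 0, k_d = 0, e0 = 0.1),
    trials_per_cell = 4000, seed = 13)
  wd <- gen_work_delay_sessions(cfg)
  rates <- tapply(wd$outcome != "correct",
                  interaction(wd$trial_type, wd$remaining_cu), mean)
  expect_true(all(abs(rates - 0.1) < 0.02))
})

test_that("delay durations follow the three cued ranges", {
  cfg <- behavior_sim_config("work_delay",
    conditions = data.frame(condition = "CON", k_w = 0.1, k_d = 0.1,
                            e0 = 0.05),
    trials_per_cell = 3000, seed = 6)
  wd <- gen_work_delay_sessions(cfg)
  del <- wd[wd$trial_type == "delay", ]
  m <- tapply(del$delay_s, del$remaining_cu, mean)
  expect_equal(as.numeric(m), c(0.3, 3.6, 7.2), tolerance = 0.03)
  rng <- tapply(del$delay_s, del$remaining_cu, range)
  expect_true(all(rng[["0"]] >= 0.2 & rng[["0"]] <= 0.4))
  expect_true(all(rng[["1"]] >= 3.0 & rng[["1"]] <= 4.2))
  expect_true(all(rng[["2"]] >= 6.0 & rng[["2"]] <= 8.4))
  expect_true(all(is.na(wd$delay_s[wd$trial_type == "work"])))
})

test_that("repeat-until-success stream re-presents refused trials", {
  cfg <- behavior_sim_config("work_delay",
    conditions = data.frame(condition = "CON", k_w = 0.3, k_d = 0.3,
                            e0 = 0.1),
    trials_per_cell = 500, repeat_refused_trials = TRUE, seed = 8)
  wd <- gen_work_delay_sessions(cfg)
  cfg$repeat_refused_trials <- FALSE
  wd_indep <- gen_work_delay_sessions(cfg)
  # repeats add presentations beyond the scheduled trial count
  expect_gt(nrow(wd), nrow(wd_indep))
  # per cell, corrects equal the scheduled count (each chain ends in success)
  ok <- wd[wd$outcome == "correct", ]
  counts <- table(interaction(ok$trial_type, ok$remaining_cu))
  expect_true(all(counts == 500))
})

test_that("negative intercepts warn and clip rather than fail", {
  expect_warning(
    behavior_sim_config("work_delay",
      conditions = data.frame(condition = "CON", k_w = 0.1, k_d = 0.1,
                              e0 = -0.2)),
    "clip")
})

test_that("trials tables round-trip through the CSV schema", {
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = "CON", a = 5, e = 0),
    trials_per_cell = 20, seed = 1)
  tr <- gen_reward_size_sessions(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(tr, path)
  back <- read_trials_csv(path)
  expect_equal(back$outcome, tr$outcome)
  expect_equal(back$rt_ms, tr$rt_ms, tolerance = 1e-9)
})
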