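test_that("outcome classification implements the (200, 1000] ms window", {
  expect_equal(classify_trial_outcome(c(-50, 150, 200, 201, 500, 1000,
                                        1001, 1200, NA)),
               c("early", "early", "early", "correct", "correct", "correct",
                 "late", "late", "late"))
})

test_that("presentations before the first correct trial are excluded", {
  trials <- data.frame(
    monkey = "M", session = "s1", condition = "CON", task = "reward_size",
    trial_type = "n/a", level = 1,
    outcome = c("early", "late", "correct", "early", "correct"),
    rt_ms = c(NA, NA, 400, NA, 420))
  tab <- aggregate_refusal(trials)
  expect_equal(tab$presentations, 3L)  # first two dropped
  expect_equal(tab$refusals, 1L)
  expect_equal(tab$refusal_rate, 1 / 3)
  expect_equal(tab$mean_rt_ms, 410)
})

test_that("all-correct input gives zero refusal rates and counts conserve", {
  trials <- data.frame(
    monkey = "M", session = rep(c("s1", "s2"), each = 4),
    condition = "CON", task = "reward_size", trial_type = "n/a",
    level = rep(c(1, 2), 4), outcome = "correct", rt_ms = 300)
  tab <- aggregate_refusal(trials)
  expect_true(all(tab$refusal_rate == 0))
  expect_equal(sum(tab$presentations), 8L)
})

test_that("refusals plus corrects equal presentations in every cell", {
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = c("CON", "MO"), a = c(6, 3),
                            e = c(0.02, 0.05)),
    trials_per_cell = 300, seed = 19)
  tr <- gen_reward_size_sessions(cfg)
  tab <- aggregate_refusal(tr)
  corr <- aggregate_refusal(tr, pool_early_late = FALSE)
  expect_equal(tab$refusals + round((1 - tab$refusal_rate) *
                                      tab$presentations),
               tab$presentations)
  # early + late rates decompose the pooled refusal rate
  expect_equal(corr$early_rate + corr$late_rate, corr$refusal_rate,
               tolerance = 1e-12)
  # 3 refusals in 10 presentations is a rate of 0.3 (arithmetic contract)
  expect_equal(unique(tab$refusals / tab$presentations),
               unique(tab$refusal_rate))
})

test_that("empty cells are absent rather than zero", {
  trials <- data.frame(
    monkey = "M", session = "s1", condition = "CON", task = "reward_size",
    trial_type = "n/a", level = c(1, 1, 2),
    outcome = c("correct", "early", "correct"), rt_ms = c(300, NA, 310))
  tab <- aggregate_refusal(trials)
  expect_equal(nrow(tab), 2L)  # only levels 1 and 2, no phantom cells
  expect_false(any(is.na(tab$refusal_rate)))
})

test_that("sucrose preference index follows its closed form", {
  expect_equal(sucrose_preference_index(200, 200), 0)
  expect_equal(sucrose_preference_index(250, 0), 1)
  expect_equal(sucrose_preference_index(300, 100), 0.5)
  expect_error(sucrose_preference_index(0, 0), "positive")
})
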