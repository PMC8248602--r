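test_that("noiseless inverse-model rates are recovered exactly by model #1", {
  a_true <- 4.2
  sizes <- c(1, 2, 4, 8)
  tab <- rates_to_refusal_table(list(CON = 1 / (a_true * sizes)), sizes,
                                n = 10000L)
  fam <- fit_reward_size_family(tab, likelihood = "gaussian")
  expect_equal(unname(fam$models[[1]]$a["CON"]), a_true, tolerance = 1e-3)
  expect_equal(fam$selected, 1L)
})

test_that("binomial MLE recovers the generating incentive impact", {
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = "CON", a = 5.2, e = 0),
    trials_per_cell = 2000, seed = 1)
  tab <- aggregate_refusal(gen_reward_size_sessions(cfg))
  fam <- fit_reward_size_family(tab)
  expect_lt(abs(unname(fam$models[[1]]$a["CON"]) - 5.2), 0.2)
})

test_that("log-likelihood is non-decreasing from nested models to the full model", {
  for (seed in 1:5) {
    cfg <- behavior_sim_config("reward_size",
      conditions = data.frame(condition = c("CON", "MO", "HO"),
                              a = c(8, 5, 3.5), e = c(0, 0.05, 0.1)),
      trials_per_cell = 400, seed = seed)
    tab <- aggregate_refusal(gen_reward_size_sessions(cfg))
    fam <- fit_reward_size_family(tab)
    logl <- vapply(fam$models, `[[`, numeric(1), "logL")
    expect_true(all(logl[4] >= logl[1:3] - 1e-6))
  }
})

test_that("normalized incentive impact of the control condition is 1", {
  cfg <- behavior_sim_config("reward_size",
    conditions = data.frame(condition = c("CON", "HO"), a = c(8, 4),
                            e = c(0, 0)),
    trials_per_cell = 300, seed = 3)
  fam <- fit_reward_size_family(aggregate_refusal(
    gen_reward_size_sessions(cfg)))
  expect_identical(unname(fam$normalized_a["CON"]), 1)
  expect_named(fam$normalized_a, c("CON", "HO"))
})

test_that("fitted inverse-model rate decreases in reward size", {
  tab <- rates_to_refusal_table(list(CON = 1 / (5 * c(1, 2, 4, 8)) + 0.03),
                                c(1, 2, 4, 8), n = 5000L)
  fam <- fit_reward_size_family(tab)
  sel <- fam$models[[fam$selected]]
  pred <- 1 / (sel$a["CON"] * c(1, 2, 4, 8)) + sel$e["CON"]
  expect_true(all(diff(pred) < 0))
})

test_that("MLE error shrinks as presentations per cell grow", {
  err <- vapply(c(200, 2000, 20000), function(n) {
    cfg <- behavior_sim_config("reward_size",
      conditions = data.frame(condition = "CON", a = 5.2, e = 0),
      trials_per_cell = n, seed = 41)
    fam <- fit_reward_size_family(aggregate_refusal(
      gen_reward_size_sessions(cfg)))
    abs(unname(fam$models[[1]]$a["CON"]) - 5.2)
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("gaussian and binomial modes report their BIC sample sizes", {
  tab <- rates_to_refusal_table(list(CON = 1 / (5 * c(1, 2, 4, 8)),
                                     HO = 1 / (2.5 * c(1, 2, 4, 8))),
                                c(1, 2, 4, 8), n = 1000L)
  fb <- fit_reward_size_family(tab, likelihood = "binomial")
  fg <- fit_reward_size_family(tab, likelihood = "gaussian")
  expect_equal(fb$models[[1]]$n, sum(tab$presentations))
  expect_equal(fg$models[[1]]$n, nrow(tab))
})

test_that("model comparison table has four rows and flags the selection", {
  tab <- rates_to_refusal_table(list(CON = 1 / (5 * c(1, 2, 4, 8)),
                                     HO = 1 / (2.5 * c(1, 2, 4, 8))),
                                c(1, 2, 4, 8), n = 1000L)
  fam <- fit_reward_size_family(tab)
  mc <- model_comparison_table(fam)
  expect_equal(nrow(mc), 4L)
  expect_equal(sum(mc$selected), 1L)
  expect_equal(min(mc$delta_BIC), 0)
})
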