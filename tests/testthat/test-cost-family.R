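make_cost_table <- function(k_w, k_d, e0, monkeys = "M1",
                            conditions = "CON", noise = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (m in monkeys) for (cond in conditions) {
    for (type in c("work", "delay")) for (cu in 0:2) {
      k <- if (type == "work") k_w[[cond]] else k_d[[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        monkey = m, condition = cond, trial_type = type, level = cu,
        refusal_rate = k * cu + e0[[cond]] + rnorm(1, 0, noise),
        mean_rt_ms = 300, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("noiseless linear cost data are recovered exactly", {
  tab <- make_cost_table(k_w = list(CON = 0.15), k_d = list(CON = 0.10),
                         e0 = list(CON = 0.05))
  fit <- fit_cost_family(tab)
  expect_equal(fit$params$k_w, 0.15, tolerance = 1e-10)
  expect_equal(fit$params$k_d, 0.10, tolerance = 1e-10)
  expect_equal(fit$params$e0, 0.05, tolerance = 1e-10)
})

test_that("zero-slope data give k = 0 and E0 equal to the mean rate", {
  tab <- make_cost_table(k_w = list(CON = 0), k_d = list(CON = 0),
                         e0 = list(CON = 0.2))
  fit <- fit_cost_family(tab)
  expect_equal(fit$params$k_w, 0, tolerance = 1e-10)
  expect_equal(fit$params$k_d, 0, tolerance = 1e-10)
  expect_equal(fit$params$e0, 0.2, tolerance = 1e-10)
})

test_that("one shared intercept spans both trial types per condition", {
  tab <- make_cost_table(
    k_w = list(CON = 0.05, HO = 0.25), k_d = list(CON = 0.08, HO = 0.25),
    e0 = list(CON = 0.03, HO = 0.08), conditions = c("CON", "HO"),
    noise = 0.01, seed = 2)
  fit <- fit_cost_family(tab)
  # exactly one E0 per condition, used by both work and delay predictions
  expect_equal(names(fit$params), c("condition", "k_w", "k_d", "e0"))
  expect_equal(nrow(fit$params), 2L)
})

test_that("per-unit coefficients equal the closed-form OLS on cell rates", {
  tab <- make_cost_table(k_w = list(CON = 0.12), k_d = list(CON = 0.07),
                         e0 = list(CON = 0.04), noise = 0.02, seed = 5)
  fit <- fit_cost_family(tab)
  # oracle: solve the 3-column normal equations directly
  X <- cbind(1, tab$level * (tab$trial_type == "work"),
             tab$level * (tab$trial_type == "delay"))
  beta <- solve(t(X) %*% X, t(X) %*% tab$refusal_rate)
  expect_equal(fit$params$e0, beta[1], tolerance = 1e-10)
  expect_equal(fit$params$k_w, beta[2], tolerance = 1e-10)
  expect_equal(fit$params$k_d, beta[3], tolerance = 1e-10)
})

test_that("faceted variants carry the right parameter counts and BIC sums", {
  tab <- make_cost_table(
    k_w = list(CON = 0.05, HO = 0.2), k_d = list(CON = 0.1, HO = 0.2),
    e0 = list(CON = 0.03, HO = 0.08), monkeys = c("M1", "M2"),
    conditions = c("CON", "HO"), noise = 0.015, seed = 7)
  fit <- fit_cost_family(tab)
  p <- vapply(fit$variants, `[[`, numeric(1), "n_params")
  # units: 4 (monkey x cond), 2 (cond), 2 (monkey), 1 (pooled) x 4 params
  expect_equal(p, c(16, 8, 8, 4))
  mc <- model_comparison_table(fit)
  expect_equal(nrow(mc), 4L)
  expect_equal(sum(mc$selected), 1L)
})

test_that("strong condition differences select a condition-faceted variant", {
  tab <- make_cost_table(
    k_w = list(CON = 0.03, MO = 0.15, HO = 0.3),
    k_d = list(CON = 0.08, MO = 0.15, HO = 0.3),
    e0 = list(CON = 0.03, MO = 0.05, HO = 0.1),
    monkeys = c("M1", "M2"), conditions = c("CON", "MO", "HO"),
    noise = 0.01, seed = 11)
  fit <- fit_cost_family(tab)
  expect_true(fit$selected %in% c(1L, 2L))
})

test_that("missing trial types and out-of-range fits are handled", {
  tab <- make_cost_table(k_w = list(CON = 0.1), k_d = list(CON = 0.1),
                         e0 = list(CON = 0.05))
  expect_error(fit_cost_family(tab[tab$trial_type == "work", ]),
               "both work and delay")
  hot <- make_cost_table(k_w = list(CON = 0.5), k_d = list(CON = 0.5),
                         e0 = list(CON = 0.4))
  hot$refusal_rate <- pmin(1, hot$refusal_rate) + 0.1 * (hot$level == 2)
  expect_warning(fit_cost_family(hot), "outside \\[0, 1\\]")
})
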