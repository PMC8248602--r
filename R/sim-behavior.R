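# Trial-level generators for the two operant tasks. Each row is one
# presentation of a cue; outcome is correct / early / late, with early+late
# jointly constituting a refusal.

rt_for_cell <- function(config, condition, e_cell, n) {
  slope <- config$rt_slope
  if (!is.null(config$rt_cond_slopes)) {
    slope <- slope + config$rt_cond_slopes[[condition]]
  }
  rt <- config$rt_intercept + slope * e_cell +
    stats::rnorm(n, 0, config$rt_noise_sd)
  # keep simulated correct releases inside the (200, 1000] ms window
  pmin(1000, pmax(201, rt))
}

# Draw outcomes/RTs for n presentations of one cell. Returns a data.frame
# with outcome, release_ms, rt_ms. `refused` may be supplied (repeat-chain
# mode) instead of drawn.
sim_cell_presentations <- function(config, condition, p_refuse, n,
                                   refused = NULL) {
  if (is.null(refused)) refused <- stats::runif(n) < p_refuse
  outcome <- character(n)
  release <- rep(NA_real_, n)
  # refusals split between early and late releases; the model pools them
  early <- refused & stats::runif(n) < 0.5
  outcome[refused & early] <- "early"
  outcome[refused & !early] <- "late"
  release[refused & early] <- stats::runif(sum(refused & early), -200, 200)
  n_ok <- sum(!refused)
  if (n_ok > 0) {
    outcome[!refused] <- "correct"
    release[!refused] <- rt_for_cell(config, condition, p_refuse, n_ok)
  }
  data.frame(outcome = outcome, release_ms = release,
             rt_ms = ifelse(outcome == "correct", release, NA_real_))
}

clip01 <- function(p) pmin(1, pmax(0, p))

# Expand independent scheduled trials into a repeat-until-success
# presentation stream: each scheduled trial becomes a chain of refused
# presentations ending in a correct one (chain length capped). Returns the
# refusal indicator over the whole presentation stream.
expand_repeats <- function(p_refuse, n_sched, max_repeats = 1000L) {
  unlist(lapply(seq_len(n_sched), function(i) {
    k <- 1L
    while (stats::runif(1) < p_refuse && k < max_repeats) k <- k + 1L
    c(rep(TRUE, k - 1L), FALSE)
  }), use.names = FALSE)
}

#' Generate synthetic reward-size task sessions
#'
#' Simulates trial-level records of the reward-size task: on each trial a
#' cue signals the reward magnitude (drops), drawn randomly with equal
#' probability, and the refusal probability of the cell is
#' `clip(1/(a R) + e, 0, 1)` with condition-specific incentive impact `a`
#' and intercept `e`. Reaction times of correct trials follow the linear
#' refusal-rate relation in the config; refused trials carry no RT.
#'
#' @param config a [behavior_sim_config()] with `task = "reward_size"`.
#' @return data.frame of presentations with columns `monkey`, `session`,
#'   `condition`, `task`, `trial_type`, `level`, `remaining_cu`,
#'   `reward_drops`, `outcome`, `release_ms`, `rt_ms`.
#' @examples
#' cfg <- behavior_sim_config("reward_size",
#'   conditions = data.frame(condition = c("CON", "HO"),
#'                           a = c(8, 4), e = c(0, 0)),
#'   trials_per_cell = 50, seed = 2)
#' trials <- gen_reward_size_sessions(cfg)
#' table(trials$condition, trials$outcome)
#' @export
gen_reward_size_sessions <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"),
            config$task == "reward_size")
  out <- list()
  for (ci in seq_len(nrow(config$conditions))) {
    cc <- config$conditions[ci, ]
    set.seed(substream_seed(config$seed, paste0("reward/", cc$condition)))
    n_total <- config$trials_per_cell * length(config$reward_sizes)
    sizes <- sample(config$reward_sizes, n_total, replace = TRUE)
    p_by_size <- clip01(1 / (cc$a * config$reward_sizes) + cc$e)
    names(p_by_size) <- as.character(config$reward_sizes)
    rows <- list()
    for (R in config$reward_sizes) {
      idx <- which(sizes == R)
      if (length(idx) == 0) next
      p <- p_by_size[[as.character(R)]]
      refused <- NULL
      n_pres <- length(idx)
      if (config$repeat_refused_trials) {
        refused <- expand_repeats(p, length(idx))
        n_pres <- length(refused)
      }
      cell <- sim_cell_presentations(config, cc$condition, p, n_pres,
                                     refused)
      cell$reward_drops <- R
      rows[[length(rows) + 1L]] <- cell
    }
    cond_tab <- do.call(rbind, rows)
    # shuffle so reward sizes interleave within the session
    cond_tab <- cond_tab[sample.int(nrow(cond_tab)), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      monkey = config$monkey,
      session = paste0(cc$condition, "_s1"),
      condition = cc$condition, task = "reward_size",
      trial_type = "n/a", level = cond_tab$reward_drops,
      remaining_cu = NA_integer_, reward_drops = cond_tab$reward_drops,
      outcome = cond_tab$outcome, release_ms = cond_tab$release_ms,
      rt_ms = cond_tab$rt_ms, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# mean 0.3 (0.2-0.4), 3.6 (3.0-4.2), 7.2 (6.0-8.4) s for 0/1/2 remaining CU
delay_ranges <- cbind(lo = c(0.2, 3.0, 6.0), hi = c(0.4, 4.2, 8.4))

#' Generate synthetic work/delay task sessions
#'
#' Simulates the work/delay task: cues signal the trial type (work or delay)
#' and the remaining cost units (CU) before reward. The refusal probability
#' is `clip(k_type CU + E0, 0, 1)` with workload (`k_w`) and delay (`k_d`)
#' discounting slopes sharing the intercept `E0` within a condition. Delay
#' trials carry a delay duration drawn uniformly from 0.2-0.4, 3.0-4.2 or
#' 6.0-8.4 s for 0, 1 or 2 remaining CU (means 0.3, 3.6, 7.2 s).
#'
#' @param config a [behavior_sim_config()] with `task = "work_delay"`.
#' @return data.frame of presentations with the trials-table schema (as in
#'   [gen_reward_size_sessions()]) plus a `delay_s` column.
#' @export
gen_work_delay_sessions <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"),
            config$task == "work_delay")
  out <- list()
  for (ci in seq_len(nrow(config$conditions))) {
    cc <- config$conditions[ci, ]
    set.seed(substream_seed(config$seed, paste0("workdelay/", cc$condition)))
    rows <- list()
    for (type in c("work", "delay")) {
      k <- if (type == "work") cc$k_w else cc$k_d
      for (cu in config$cost_units) {
        p <- clip01(k * cu + cc$e0)
        refused <- NULL
        n_pres <- config$trials_per_cell
        if (config$repeat_refused_trials) {
          refused <- expand_repeats(p, config$trials_per_cell)
          n_pres <- length(refused)
        }
        if (n_pres == 0) next
        cell <- sim_cell_presentations(config, cc$condition, p, n_pres,
                                       refused)
        cell$trial_type <- type
        cell$remaining_cu <- cu
        cell$delay_s <- NA_real_
        if (type == "delay" && cu + 1L <= nrow(delay_ranges)) {
          cell$delay_s <- stats::runif(n_pres, delay_ranges[cu + 1L, "lo"],
                                       delay_ranges[cu + 1L, "hi"])
        }
        rows[[length(rows) + 1L]] <- cell
      }
    }
    cond_tab <- do.call(rbind, rows)
    cond_tab <- cond_tab[sample.int(nrow(cond_tab)), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      monkey = config$monkey,
      session = paste0(cc$condition, "_s1"),
      condition = cc$condition, task = "work_delay",
      trial_type = cond_tab$trial_type, level = cond_tab$remaining_cu,
      remaining_cu = cond_tab$remaining_cu, reward_drops = NA_real_,
      outcome = cond_tab$outcome, release_ms = cond_tab$release_ms,
      rt_ms = cond_tab$rt_ms, delay_s = cond_tab$delay_s,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
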