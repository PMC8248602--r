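#' Configuration for the synthetic PET study generator
#'
#' Defines the regions, SRTM kinetic parameters, frame schedule, per-condition
#' ground-truth occupancy and noise level used by [gen_pet_study()].
#'
#' @param regions data.frame with columns `region` (label), `bp_nd` (baseline
#'   binding potential, unitless, >= 0), `r1` (delivery ratio relative to the
#'   reference region, unitless) and `k2` (clearance rate, 1/min, > 0).
#' @param frames two-column matrix or data.frame of frame start/end times in
#'   minutes; frames must be increasing and non-overlapping. The default is a
#'   typical 60-min dynamic schedule (6 x 0.5, 3 x 1, 5 x 2, 11 x 4 min).
#' @param occupancy_truth named numeric vector of true fractional blockade per
#'   condition (0 to 1). A `"baseline"` condition with occupancy 0 is always
#'   generated in addition.
#' @param noise_sd Gaussian frame-noise standard deviation expressed as a
#'   fraction of the peak reference-region activity (0 disables noise).
#' @param seed integer master seed.
#'
#' @return An object of class `pet_sim_config`.
#' @seealso [gen_pet_study()]
#' @export
pet_sim_config <- function(regions = default_pet_regions(),
                           frames = default_frame_schedule(),
                           occupancy_truth = c(treatment = 0.5),
                           noise_sd = 0,
                           seed = 1L) {
  regions <- as.data.frame(regions)
  needed <- c("region", "bp_nd", "r1", "k2")
  if (!all(needed %in% names(regions))) {
    stop("`regions` must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$bp_nd < 0)) stop("bp_nd must be >= 0", call. = FALSE)
  if (any(regions$k2 <= 0)) stop("k2 must be > 0", call. = FALSE)
  frames <- validate_frames(frames)
  if (is.null(names(occupancy_truth)) || any(!nzchar(names(occupancy_truth)))) {
    stop("`occupancy_truth` must be a named vector of conditions", call. = FALSE)
  }
  if (any(occupancy_truth < 0 | occupancy_truth > 1)) {
    stop("occupancy_truth values must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(regions = regions, frames = frames,
         occupancy_truth = occupancy_truth,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "pet_sim_config"
  )
}

#' Default brain regions for PET simulation
#'
#' A realistic spread of baseline binding potentials from high-binding
#' striatal regions to low-binding cortex, with modest variation in delivery
#' and clearance.
#'
#' @return data.frame with columns `region`, `bp_nd`, `r1`, `k2`.
#' @export
default_pet_regions <- function() {
  data.frame(
    region = c("putamen", "caudate", "nacc", "thalamus", "hippocampus",
               "amygdala", "parietal", "dlpfc", "vlpfc", "principal_sulcus"),
    bp_nd = c(3.5, 3.2, 2.6, 1.4, 1.0, 0.9, 0.55, 0.45, 0.35, 0.2),
    r1 = c(1.15, 1.1, 1.05, 1.0, 0.95, 0.95, 0.9, 0.92, 0.9, 0.88),
    k2 = c(0.10, 0.10, 0.11, 0.12, 0.11, 0.12, 0.13, 0.13, 0.13, 0.14),
    stringsAsFactors = FALSE
  )
}

#' Default 60-minute dynamic frame schedule
#'
#' @return two-column matrix of frame start/end times (min).
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 5), rep(4, 11))
  ends <- cumsum(dur)
  cbind(start = c(0, ends[-length(ends)]), end = ends)
}

validate_frames <- function(frames) {
  frames <- as.matrix(frames)
  if (ncol(frames) != 2) stop("frames must have 2 columns (start, end)",
                              call. = FALSE)
  storage.mode(frames) <- "double"
  colnames(frames) <- c("start", "end")
  if (any(frames[, 2] <= frames[, 1])) {
    stop("invalid frame schedule: frame end must exceed start", call. = FALSE)
  }
  if (nrow(frames) > 1 &&
      any(frames[-1, 1] < frames[-nrow(frames), 2] - 1e-9)) {
    stop("invalid frame schedule: frames overlap or are out of order",
         call. = FALSE)
  }
  frames
}

#' Configuration for synthetic operant-session generators
#'
#' Ground-truth behavioral parameters per treatment condition for the
#' reward-size task (refusal rate E = 1/(a R) + e over reward sizes in drops)
#' or the work/delay task (E = k CU + E0 over remaining cost units).
#'
#' @param task `"reward_size"` or `"work_delay"`.
#' @param conditions data.frame of per-condition truth. For `reward_size`:
#'   columns `condition`, `a` (incentive impact, 1/drop, > 0), `e`
#'   (reward-independent refusal rate). For `work_delay`: columns `condition`,
#'   `k_w` (workload discounting per CU), `k_d` (delay discounting per CU),
#'   `e0` (shared intercept).
#' @param reward_sizes reward magnitudes in drops (reward-size task).
#' @param cost_units remaining cost-unit levels (work/delay task).
#' @param trials_per_cell presentations generated per condition x level cell
#'   (x trial type for work/delay).
#' @param rt_intercept,rt_slope,rt_cond_slopes,rt_noise_sd reaction-time model
#'   for correct trials: RT (ms) = `rt_intercept` + (`rt_slope` +
#'   `rt_cond_slopes[condition]`) * E_cell + Gaussian noise. The default
#'   places RTs in the 250-400 ms range typical of bar-release tasks.
#' @param repeat_refused_trials if TRUE the generator emulates the task's
#'   repeat-until-success presentation stream: each scheduled trial is
#'   re-presented until performed correctly, every presentation a row.
#' @param monkey subject label written to the output table.
#' @param seed integer master seed.
#'
#' @return An object of class `behavior_sim_config`.
#' @seealso [gen_reward_size_sessions()], [gen_work_delay_sessions()]
#' @export
behavior_sim_config <- function(task = c("reward_size", "work_delay"),
                                conditions,
                                reward_sizes = c(1, 2, 4, 8),
                                cost_units = 0:2,
                                trials_per_cell = 500L,
                                rt_intercept = 280,
                                rt_slope = 150,
                                rt_cond_slopes = NULL,
                                rt_noise_sd = 25,
                                repeat_refused_trials = FALSE,
                                monkey = "SIM",
                                seed = 1L) {
  task <- match.arg(task)
  conditions <- as.data.frame(conditions)
  if (!"condition" %in% names(conditions)) {
    stop("`conditions` must have a `condition` column", call. = FALSE)
  }
  if (task == "reward_size") {
    if (!all(c("a", "e") %in% names(conditions))) {
      stop("reward_size conditions need columns `a` and `e`", call. = FALSE)
    }
    if (any(conditions$a <= 0)) stop("a must be > 0", call. = FALSE)
  } else {
    if (!all(c("k_w", "k_d", "e0") %in% names(conditions))) {
      stop("work_delay conditions need columns `k_w`, `k_d`, `e0`",
           call. = FALSE)
    }
    if (any(conditions$e0 < 0)) {
      warning("negative E0: refusal probabilities will be clipped at 0")
    }
  }
  if (trials_per_cell < 0) stop("trials_per_cell must be >= 0", call. = FALSE)
  if (!is.null(rt_cond_slopes) &&
      !all(conditions$condition %in% names(rt_cond_slopes))) {
    stop("rt_cond_slopes must name every condition", call. = FALSE)
  }
  structure(
    list(task = task, conditions = conditions,
         reward_sizes = reward_sizes, cost_units = sort(unique(cost_units)),
         trials_per_cell = as.integer(trials_per_cell),
         rt_intercept = rt_intercept, rt_slope = rt_slope,
         rt_cond_slopes = rt_cond_slopes, rt_noise_sd = rt_noise_sd,
         repeat_refused_trials = isTRUE(repeat_refused_trials),
         monkey = monkey, seed = as.integer(seed)),
    class = "behavior_sim_config"
  )
}

#' Configuration for synthetic occupancy-series generation
#'
#' Dose mode draws occupancies from the one-parameter Hill relation
#' Occ(%) = 100 Dose / (ED50 + Dose); day mode from the exponential washout
#' Occ(%) = Occ_Day0 exp(-lambda Day). Gaussian noise (percentage points) is
#' added and values truncated to \[0, 100\].
#'
#' @param mode `"dose"` or `"day"`.
#' @param ed50 half-occupancy dose (ug/kg, dose mode, > 0).
#' @param occ_day0 day-0 occupancy (%, day mode, in \[0, 100\]).
#' @param lambda washout rate (1/day, day mode, >= 0).
#' @param design_points doses (ug/kg) or days at which to observe.
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param replicates independent replicate series.
#' @param seed integer master seed.
#'
#' @return An object of class `occupancy_series_config`.
#' @seealso [gen_occupancy_series()]
#' @export
occupancy_series_config <- function(mode = c("dose", "day"),
                                    ed50 = NULL,
                                    occ_day0 = NULL, lambda = NULL,
                                    design_points,
                                    noise_sd = 0,
                                    replicates = 1L,
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "dose") {
    if (is.null(ed50) || ed50 <= 0) {
      stop("dose mode requires ed50 > 0", call. = FALSE)
    }
    if (!is.null(occ_day0) || !is.null(lambda)) {
      stop("occ_day0/lambda are day-mode parameters", call. = FALSE)
    }
    if (any(design_points < 0)) stop("doses must be >= 0", call. = FALSE)
  } else {
    if (is.null(occ_day0) || is.null(lambda)) {
      stop("day mode requires occ_day0 and lambda", call. = FALSE)
    }
    if (occ_day0 < 0 || occ_day0 > 100) {
      stop("occ_day0 must lie in [0, 100]", call. = FALSE)
    }
    if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
    if (!is.null(ed50)) stop("ed50 is a dose-mode parameter", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(mode = mode, ed50 = ed50, occ_day0 = occ_day0, lambda = lambda,
         design_points = design_points, noise_sd = noise_sd,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "occupancy_series_config"
  )
}

# Derive a deterministic 32-bit substream seed from a master seed and a
# stream label, so independent generators never share a random stream.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}
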