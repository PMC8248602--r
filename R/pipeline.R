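# End-to-end orchestration: simulate -> fit PET -> fit behavior -> report.

#' Default demonstration run configuration
#'
#' A complete [run_pipeline()] configuration emulating the study design:
#' a baseline plus moderate- (MO, 50%) and high-occupancy (HO, 80%) PET
#' conditions, dose- and day-mode occupancy series, and reward-size and
#' work/delay sessions whose ground truth shows the signature effects
#' (incentive impact halved at HO; cost discounting increasing with
#' occupancy).
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return An object of class `run_config` (a named list of sub-configs).
#' @export
default_run_config <- function(seed = 1L) {
  run_config(
    pet = pet_sim_config(
      occupancy_truth = c(MO = 0.5, HO = 0.8),
      noise_sd = 0.005, seed = seed),
    occupancy_series = list(
      dose = occupancy_series_config(
        "dose", ed50 = 22.63, design_points = c(10, 30, 50, 100),
        noise_sd = 3, replicates = 3, seed = seed),
      day = occupancy_series_config(
        "day", occ_day0 = 78, lambda = log(78 / 48),
        design_points = c(0, 1, 2, 3, 7), noise_sd = 3, replicates = 3,
        seed = seed)),
    reward = behavior_sim_config(
      "reward_size",
      conditions = data.frame(condition = c("CON", "MO", "HO"),
                              a = c(8, 5.4, 4), e = c(0, 0, 0)),
      trials_per_cell = 500L, seed = seed),
    work_delay = behavior_sim_config(
      "work_delay",
      conditions = data.frame(condition = c("CON", "MO", "HO"),
                              k_w = c(0.05, 0.15, 0.25),
                              k_d = c(0.08, 0.15, 0.25),
                              e0 = c(0.03, 0.05, 0.08)),
      trials_per_cell = 400L, seed = seed),
    occupancy_map = c(CON = 0, MO = 50, HO = 80),
    seed = seed
  )
}

#' Assemble a pipeline run configuration
#'
#' @param pet a [pet_sim_config()] (or NULL to skip the PET stage).
#' @param occupancy_series named list of [occupancy_series_config()]s;
#'   dose-mode entries are calibrated with [fit_hill()], day-mode entries
#'   with [fit_decay()].
#' @param reward a [behavior_sim_config()] for the reward-size task.
#' @param work_delay a [behavior_sim_config()] for the work/delay task.
#' @param occupancy_map named numeric vector mapping behavioral condition
#'   labels to nominal occupancy (%), e.g. `c(CON = 0, MO = 50, HO = 80)`.
#' @param seed master seed; stage substreams are derived deterministically.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pet = NULL, occupancy_series = list(),
                       reward = NULL, work_delay = NULL,
                       occupancy_map = NULL, seed = 1L) {
  cfg <- structure(
    list(pet = pet, occupancy_series = occupancy_series, reward = reward,
         work_delay = work_delay, occupancy_map = occupancy_map,
         seed = as.integer(seed)),
    class = "run_config"
  )
  # propagate the master seed into every stage for end-to-end determinism
  if (!is.null(cfg$pet)) cfg$pet$seed <- substream_seed(seed, "stage/pet")
  cfg$occupancy_series <- lapply(cfg$occupancy_series, function(oc) {
    oc$seed <- substream_seed(seed, paste0("stage/occ/", oc$mode))
    oc
  })
  if (!is.null(cfg$reward)) {
    cfg$reward$seed <- substream_seed(seed, "stage/reward")
  }
  if (!is.null(cfg$work_delay)) {
    cfg$work_delay$seed <- substream_seed(seed, "stage/workdelay")
  }
  cfg
}

config_hash <- function(config) {
  json <- jsonlite::serializeJSON(unclass(config))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-fit-report pipeline
#'
#' Executes the stages in order on synthetic data: PET TAC generation and
#' SRTM fitting per region and condition, per-condition occupancy
#' estimation (Lassen regression across regions, plus the per-region
#' binding-potential ratio for the highest-binding region), dose/day
#' occupancy-series calibration, behavioral session generation, refusal
#' aggregation, and the three behavioral model families. Identical
#' config and seed yield an identical report.
#'
#' @param config a [run_config()], e.g. [default_run_config()].
#' @return An object of class `run_report`: list with `occupancy_table`,
#'   `bp_table`, `hill` / `decay` models, `reward_fit`, `cost_fit`,
#'   `rt_fit`, `incentive_occupancy`, the refusal tables, and `provenance`
#'   (config hash, seed, package/R versions).
#' @examples
#' \donttest{
#' report <- run_pipeline(default_run_config(seed = 42))
#' report$occupancy_table
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list()

  if (!is.null(config$pet)) {
    tacs <- gen_pet_study(config$pet)
    conds <- unique(tacs$condition)
    regions <- setdiff(unique(tacs$region), "cerebellum")
    bp_rows <- list()
    for (cond in conds) {
      ref <- get_tac(tacs, "cerebellum", cond)
      for (rg in regions) {
        fit <- fit_srtm(get_tac(tacs, rg, cond), ref)
        bp_rows[[length(bp_rows) + 1L]] <- data.frame(
          region = rg, condition = cond, bp_nd = fit$bp_nd, r1 = fit$r1,
          k2 = fit$k2, rss = fit$rss, stringsAsFactors = FALSE)
      }
    }
    bp <- do.call(rbind, bp_rows)
    base <- bp[bp$condition == "baseline", ]
    occ_rows <- list()
    top_region <- base$region[which.max(base$bp_nd)]
    for (cond in setdiff(conds, "baseline")) {
      tr <- bp[bp$condition == cond, ]
      tr <- tr[match(base$region, tr$region), ]
      las <- lassen_occupancy(base$bp_nd, tr$bp_nd, regions = base$region)
      per <- occupancy_from_bp(base$bp_nd[base$region == top_region],
                               tr$bp_nd[tr$region == top_region])
      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        condition = cond,
        method = c("lassen_slope", "per_region"),
        occupancy_pct = c(las$occupancy, per$occupancy),
        se = c(las$se, NA_real_), stringsAsFactors = FALSE)
    }
    report$tacs <- tacs
    report$bp_table <- bp
    report$occupancy_table <- do.call(rbind, occ_rows)
  }

  for (nm in names(config$occupancy_series)) {
    oc <- config$occupancy_series[[nm]]
    obs <- gen_occupancy_series(oc)
    if (oc$mode == "dose") {
      report$hill <- fit_hill(obs$point[obs$point > 0],
                              obs$occupancy_pct[obs$point > 0])
      report$dose_series <- obs
    } else {
      report$decay <- fit_decay(obs$point, obs$occupancy_pct)
      report$day_series <- obs
    }
  }

  if (!is.null(config$reward)) {
    trials <- gen_reward_size_sessions(config$reward)
    ref_tab <- aggregate_refusal(trials)
    report$reward_refusals <- ref_tab
    report$reward_fit <- fit_reward_size_family(ref_tab)
    report$rt_fit <- fit_rt_relation_family(ref_tab)
  }
  if (!is.null(config$work_delay)) {
    trials <- gen_work_delay_sessions(config$work_delay)
    ref_tab <- aggregate_refusal(trials)
    report$work_delay_refusals <- ref_tab
    report$cost_fit <- fit_cost_family(ref_tab)
  }
  if (!is.null(report$reward_fit) && !is.null(config$occupancy_map)) {
    report$incentive_occupancy <- build_incentive_occupancy_table(
      config$occupancy_map, report$reward_fit)
  }

  report$provenance <- list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("occmot")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  class(report) <- "run_report"
  report
}

#' Join per-condition occupancy with normalized incentive impact
#'
#' Builds the (occupancy %, normalized incentive impact) pairs relating
#' receptor blockade to the reward-size model's `a` parameter, normalized
#' by the control condition. No smoothing is applied. Conditions present
#' in only one of the two inputs are excluded with a warning.
#'
#' @param occupancy named numeric vector of per-condition occupancy (%),
#'   or a data.frame with columns `condition`, `occupancy_pct`.
#' @param reward_fit a [fit_reward_size_family()] result.
#' @return data.frame with columns `condition`, `occupancy_pct`,
#'   `normalized_a`.
#' @export
build_incentive_occupancy_table <- function(occupancy, reward_fit) {
  stopifnot(inherits(reward_fit, "reward_family_fit"))
  if (is.data.frame(occupancy)) {
    occ <- stats::setNames(occupancy$occupancy_pct, occupancy$condition)
  } else {
    occ <- occupancy
  }
  shared <- intersect(names(occ), names(reward_fit$normalized_a))
  dropped <- union(setdiff(names(occ), shared),
                   setdiff(names(reward_fit$normalized_a), shared))
  if (length(dropped)) {
    warning("conditions present in only one table excluded: ",
            paste(dropped, collapse = ", "))
  }
  out <- data.frame(condition = shared,
                    occupancy_pct = unname(occ[shared]),
                    normalized_a = unname(reward_fit$normalized_a[shared]),
                    stringsAsFactors = FALSE)
  out[order(out$occupancy_pct), , drop = FALSE]
}

report_summary <- function(report) {
  num <- function(x) if (is.null(x)) NULL else unname(x)
  list(
    occupancy = if (!is.null(report$occupancy_table)) {
      lapply(split(report$occupancy_table,
                   seq_len(nrow(report$occupancy_table))), function(r) {
        list(condition = r$condition, method = r$method,
             occupancy_pct = r$occupancy_pct)
      })
    },
    hill_ed50 = num(if (!is.null(report$hill)) report$hill$ed50),
    decay = if (!is.null(report$decay)) {
      list(occ_day0 = report$decay$occ_day0, lambda = report$decay$lambda)
    },
    reward = if (!is.null(report$reward_fit)) list(
      selected_model = report$reward_fit$selected,
      a = as.list(report$reward_fit$a),
      e = as.list(report$reward_fit$e),
      normalized_a = as.list(report$reward_fit$normalized_a)),
    cost = if (!is.null(report$cost_fit)) list(
      selected_variant = report$cost_fit$selected,
      params = lapply(split(report$cost_fit$params,
                            seq_len(nrow(report$cost_fit$params))),
                      function(r) list(condition = r$condition, k_w = r$k_w,
                                       k_d = r$k_d, e0 = r$e0))),
    rt = if (!is.null(report$rt_fit)) list(
      selected_variant = report$rt_fit$selected,
      slope = as.list(report$rt_fit$slope),
      intercept = as.list(report$rt_fit$intercept)),
    provenance = report$provenance
  )
}

#' Write a pipeline report to disk
#'
#' Writes the report's tables as CSV files, the model-comparison tables
#' for each fitted family, and a JSON summary. The file set is stable:
#' `occupancy_table.csv`, `bp_table.csv`, `reward_refusals.csv`,
#' `work_delay_refusals.csv`, `incentive_occupancy.csv`,
#' `model_comparison_{reward,cost,rt}.csv`, `behavior_params.csv`,
#' `report.json` (only those whose stage ran).
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  written <- character(0)
  put_csv <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  put_csv(report$occupancy_table, "occupancy_table.csv")
  put_csv(report$bp_table, "bp_table.csv")
  put_csv(report$reward_refusals, "reward_refusals.csv")
  put_csv(report$work_delay_refusals, "work_delay_refusals.csv")
  put_csv(report$incentive_occupancy, "incentive_occupancy.csv")
  if (!is.null(report$reward_fit)) {
    put_csv(model_comparison_table(report$reward_fit),
            "model_comparison_reward.csv")
  }
  if (!is.null(report$cost_fit)) {
    put_csv(model_comparison_table(report$cost_fit),
            "model_comparison_cost.csv")
    put_csv(report$cost_fit$params, "behavior_params.csv")
  }
  if (!is.null(report$rt_fit)) {
    put_csv(model_comparison_table(report$rt_fit), "model_comparison_rt.csv")
  }
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_summary(report), jp, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  written <- c(written, jp)
  invisible(written)
}

#' @export
print.run_report <- function(x, ...) {
  cat("occmot pipeline report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$occupancy_table)) {
    cat("Occupancy:\n"); print(x$occupancy_table, row.names = FALSE)
  }
  if (!is.null(x$hill)) print(x$hill)
  if (!is.null(x$decay)) print(x$decay)
  if (!is.null(x$reward_fit)) print(x$reward_fit)
  if (!is.null(x$cost_fit)) print(x$cost_fit)
  invisible(x)
}
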