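#' Generate a synthetic PET occupancy study
#'
#' Produces dynamic time-activity curves (TACs) for every region and
#' condition in a [pet_sim_config()]. The reference region (cerebellum) TAC
#' is a fixed analytic curve ([reference_tac()]); each target region is
#' generated from the SRTM forward model with condition binding potential
#' `bp_nd * (1 - occupancy_truth)`, i.e. a uniform fractional blockade
#' across regions. Gaussian noise (SD = `noise_sd` x peak reference
#' activity) is drawn once per region and shared across conditions, so a
#' condition with zero true occupancy reproduces the baseline TAC exactly.
#'
#' @param config a [pet_sim_config()].
#' @return data.frame with columns `region`, `condition`,
#'   `frame_start_min`, `frame_end_min`, `activity_kbq_ml`. The reference
#'   region is labeled `"cerebellum"`.
#' @examples
#' tacs <- gen_pet_study(pet_sim_config(noise_sd = 0, seed = 7))
#' head(tacs)
#' @export
gen_pet_study <- function(config) {
  stopifnot(inherits(config, "pet_sim_config"))
  frames <- config$frames
  tmid <- frame_midpoints(frames)
  conditions <- c(baseline = 0, config$occupancy_truth)
  peak <- max(reference_tac(seq(0, max(frames), by = 0.05)))
  ref_act <- reference_tac(tmid)

  # one noise vector per region, reused across conditions (paired scans)
  noise_for <- function(region) {
    if (config$noise_sd == 0) return(numeric(length(tmid)))
    set.seed(substream_seed(config$seed, paste0("pet/", region)))
    stats::rnorm(length(tmid), 0, config$noise_sd * peak)
  }

  out <- list()
  ref_noise <- noise_for("cerebellum")
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    out[[length(out) + 1L]] <- data.frame(
      region = "cerebellum", condition = cond,
      frame_start_min = frames[, 1], frame_end_min = frames[, 2],
      activity_kbq_ml = ref_act + ref_noise,
      stringsAsFactors = FALSE
    )
    for (ri in seq_len(nrow(config$regions))) {
      rg <- config$regions[ri, ]
      bp <- rg$bp_nd * (1 - conditions[ci])
      ct <- srtm_forward(tmid, reference_tac, rg$r1, rg$k2, bp)
      out[[length(out) + 1L]] <- data.frame(
        region = rg$region, condition = cond,
        frame_start_min = frames[, 1], frame_end_min = frames[, 2],
        activity_kbq_ml = ct + noise_for(rg$region),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Extract one region/condition TAC from a long TAC table
#'
#' @param tacs long TAC data.frame as returned by [gen_pet_study()] or read
#'   from the TAC CSV schema.
#' @param region region label.
#' @param condition condition label.
#' @return data.frame with the TAC's rows, frame-ordered.
#' @export
get_tac <- function(tacs, region, condition) {
  sel <- tacs[tacs$region == region & tacs$condition == condition, ,
              drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no TAC for region '", region, "', condition '", condition, "'",
         call. = FALSE)
  }
  sel[order(sel$frame_start_min), , drop = FALSE]
}

#' Generate synthetic occupancy observations over doses or days
#'
#' Dose mode draws from the Hill relation Occ(%) = 100 Dose / (ED50 + Dose);
#' day mode from the exponential washout Occ(%) = Occ_Day0 exp(-lambda Day).
#' Gaussian noise in percentage points is added per observation and values
#' truncated to \[0, 100\].
#'
#' @param config an [occupancy_series_config()].
#' @return data.frame with columns `point` (dose in ug/kg or day),
#'   `replicate`, `occupancy_pct`.
#' @examples
#' cfg <- occupancy_series_config("day", occ_day0 = 78, lambda = log(78 / 48),
#'                                design_points = 0:3, noise_sd = 0)
#' gen_occupancy_series(cfg)
#' @export
gen_occupancy_series <- function(config) {
  stopifnot(inherits(config, "occupancy_series_config"))
  truth <- if (config$mode == "dose") {
    100 * config$design_points / (config$ed50 + config$design_points)
  } else {
    config$occ_day0 * exp(-config$lambda * config$design_points)
  }
  set.seed(substream_seed(config$seed, paste0("occseries/", config$mode)))
  grid <- expand.grid(point = config$design_points,
                      replicate = seq_len(config$replicates))
  vals <- rep(truth, times = config$replicates)
  if (config$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, config$noise_sd)
  }
  data.frame(point = grid$point, replicate = grid$replicate,
             occupancy_pct = pmin(100, pmax(0, vals)))
}
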