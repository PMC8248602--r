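#' Classify a bar-release trial outcome
#'
#' The task requires releasing the bar between 200 and 1,000 ms after the
#' go signal. Releases at or before 200 ms (including releases before the
#' go signal, negative times) are `early`; releases in (200, 1000] ms are
#' `correct`; releases after 1,000 ms or absent (`NA`) are `late`. Early
#' and late releases together constitute refusals.
#'
#' @param release_ms_from_go release time in ms relative to the go signal;
#'   `NA` for no release.
#' @return character vector: `"early"`, `"correct"` or `"late"`.
#' @examples
#' classify_trial_outcome(c(-50, 150, 500, 1000, 1200, NA))
#' @export
classify_trial_outcome <- function(release_ms_from_go) {
  out <- ifelse(is.na(release_ms_from_go), "late",
         ifelse(release_ms_from_go <= 200, "early",
         ifelse(release_ms_from_go <= 1000, "correct", "late")))
  unname(out)
}

#' Aggregate trial records into refusal-rate cells
#'
#' Computes per-cell refusal rates and mean reaction times from trial-level
#' records. Within each session, presentations preceding the first correct
#' trial are excluded (monkeys often refuse at session start out of
#' impatience rather than low motivation). Early and late releases are
#' pooled as refusals; set `pool_early_late = FALSE` to additionally report
#' the early/late breakdown for error-pattern description.
#'
#' @param trials data.frame with at least `session`, `outcome` and the
#'   grouping columns, in presentation order within session (the schema of
#'   [gen_reward_size_sessions()] / [gen_work_delay_sessions()]).
#' @param by grouping columns defining a cell.
#' @param pool_early_late if FALSE, add `early_rate` / `late_rate` columns.
#' @param drop_before_first_correct apply the session-start exclusion rule.
#' @return data.frame with the grouping columns plus `refusals`,
#'   `presentations`, `refusal_rate` and `mean_rt_ms` (NA when a cell has
#'   no correct trial). Cells with no presentations are absent, never 0.
#' @export
aggregate_refusal <- function(trials,
                              by = c("monkey", "condition", "task",
                                     "trial_type", "level"),
                              pool_early_late = TRUE,
                              drop_before_first_correct = TRUE) {
  stopifnot(all(c("session", "outcome") %in% names(trials)))
  by <- intersect(by, names(trials))
  if (length(by) == 0) stop("no grouping columns present", call. = FALSE)

  if (drop_before_first_correct && nrow(trials) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$session),
                          function(idx) {
      first_ok <- match("correct", trials$outcome[idx])
      if (is.na(first_ok)) integer(0) else idx[seq(first_ok, length(idx))]
    }), use.names = FALSE)
    trials <- trials[sort(keep), , drop = FALSE]
  }
  if (nrow(trials) == 0) {
    stop("no presentations remain after session-start exclusion",
         call. = FALSE)
  }

  key <- interaction(trials[by], drop = TRUE, lex.order = TRUE)
  refused <- trials$outcome %in% c("early", "late")
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  cells <- unique(data.frame(trials[by], .key = key))
  cells <- cells[order(cells$.key), , drop = FALSE]
  out <- cells[setdiff(names(cells), ".key")]
  out$refusals <- as.integer(agg(refused, sum))
  out$presentations <- as.integer(agg(refused, length))
  out$refusal_rate <- out$refusals / out$presentations
  rt <- if ("rt_ms" %in% names(trials)) trials$rt_ms else rep(NA_real_,
                                                              nrow(trials))
  rt[!trials$outcome %in% "correct"] <- NA
  out$mean_rt_ms <- agg(rt, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  if (!pool_early_late) {
    out$early_rate <- agg(trials$outcome == "early", sum) / out$presentations
    out$late_rate <- agg(trials$outcome == "late", sum) / out$presentations
  }
  rownames(out) <- NULL
  out
}

#' Sucrose preference index
#'
#' `SP = (SW - TW) / (SW + TW)` for sucrose-water intake `SW` and tap-water
#' intake `TW`; ranges from -1 (water only) to 1 (sucrose only).
#'
#' @param sucrose_ml,water_ml intake volumes (mL), with positive total.
#' @return numeric preference index in \[-1, 1\].
#' @examples
#' sucrose_preference_index(300, 100)  # 0.5
#' @export
sucrose_preference_index <- function(sucrose_ml, water_ml) {
  total <- sucrose_ml + water_ml
  if (any(total <= 0)) {
    stop("total intake must be positive", call. = FALSE)
  }
  (sucrose_ml - water_ml) / total
}
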