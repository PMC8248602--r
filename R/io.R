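# Stable CSV schemas shared by the generators, the fitters and the CLI.

tac_csv_columns <- c("region", "condition", "frame_start_min",
                     "frame_end_min", "activity_kbq_ml")
trials_csv_columns <- c("monkey", "session", "condition", "task",
                        "trial_type", "level", "remaining_cu",
                        "reward_drops", "outcome", "release_ms", "rt_ms")

#' Read / write time-activity curves in the package's TAC CSV schema
#'
#' Columns: `region, condition, frame_start_min, frame_end_min,
#' activity_kbq_ml`.
#'
#' @param path CSV file path.
#' @param tacs TAC data.frame.
#' @return `read_tacs_csv` returns the TAC data.frame; `write_tacs_csv`
#'   returns `path` invisibly.
#' @export
read_tacs_csv <- function(path) {
  tacs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(tac_csv_columns, names(tacs))
  if (length(missing)) {
    stop("TAC CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tacs
}

#' @rdname read_tacs_csv
#' @export
write_tacs_csv <- function(tacs, path) {
  utils::write.csv(tacs[tac_csv_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read / write trial records in the package's trials CSV schema
#'
#' Columns: `monkey, session, condition, task, trial_type, level,
#' remaining_cu, reward_drops, outcome, release_ms, rt_ms` (plus any extra
#' columns such as `delay_s`, preserved on write).
#'
#' @param path CSV file path.
#' @param trials trials data.frame.
#' @return `read_trials_csv` returns the trials data.frame;
#'   `write_trials_csv` returns `path` invisibly.
#' @export
read_trials_csv <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trials_csv_columns, names(trials))
  if (length(missing)) {
    stop("trials CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  extra <- setdiff(names(trials), trials_csv_columns)
  utils::write.csv(trials[c(trials_csv_columns, extra)], path,
                   row.names = FALSE)
  invisible(path)
}
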