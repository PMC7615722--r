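# CSV interfaces. One row per trial; UTF-8, comma-separated, header row;
# missing values are empty fields. Files store 1-based trial numbers and
# integer-millisecond RTs; in memory, schedules are 0-based (`index`) and
# score formulas work in seconds.

TRIAL_LOG_COLUMNS <- c("participant_id", "task", "phase", "day", "trial_number",
                       "left_stim", "right_stim", "cue_side",
                       "response_window_ms", "choice_side", "chosen_stim",
                       "outcome_points_left", "outcome_points_right",
                       "rt_ms", "missed")

#' Write a trial log or schedule to CSV
#'
#' Schedules without response columns are padded with empty response fields;
#' the internal 0-based `index` is exported as 1-based `trial_number`.
#'
#' @param log schedule or session-log data frame.
#' @param path output file path.
#' @param participant_id filled in when the log has no such column.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path, participant_id = "") {
  out <- log
  if (!"participant_id" %in% names(out)) out$participant_id <- participant_id
  if (!"trial_number" %in% names(out)) out$trial_number <- out$index + 1L
  for (col in setdiff(TRIAL_LOG_COLUMNS, names(out))) out[[col]] <- NA
  out <- out[TRIAL_LOG_COLUMNS]
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial log written by [write_trial_log()]
#'
#' @param path CSV file path.
#' @return data frame with the internal 0-based `index` restored.
#' @export
read_trial_log <- function(path) {
  log <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8",
                  colClasses = c(
                    participant_id = "character", task = "character",
                    phase = "character", day = "integer",
                    trial_number = "integer", left_stim = "character",
                    right_stim = "character", cue_side = "character",
                    response_window_ms = "integer", choice_side = "character",
                    chosen_stim = "character",
                    outcome_points_left = "integer",
                    outcome_points_right = "integer",
                    rt_ms = "integer", missed = "integer"))
  if (!identical(names(log), TRIAL_LOG_COLUMNS))
    stop("not a trial-log CSV: unexpected columns in ", path, call. = FALSE)
  log$index <- log$trial_number - 1L
  log
}

#' Write and read the ratings, questionnaire and ground-truth tables
#'
#' Thin CSV wrappers sharing the trial-log conventions (UTF-8, header row,
#' empty fields for missing values).
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `path` (writers, invisibly) or the data frame (reader).
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE,
           fileEncoding = "UTF-8")
}

#' Score a whole cohort into a one-row-per-participant table
#'
#' Applies the rewarded-pair and unrewarded log-level scores plus the rating
#' scores to every participant in a cohort's trial logs and ratings table,
#' including the training-effect magnitudes between the pre-training (day 1)
#' and final test phases.
#'
#' @param trial_logs combined trial-log data frame with `participant_id`.
#' @param ratings ratings table (`participant_id`, `stimulus`, `timepoint`,
#'   `rating`), or `NULL` to skip rating scores.
#' @return data frame with one row per participant.
#' @export
score_cohort <- function(trial_logs, ratings = NULL) {
  pids <- unique(trial_logs$participant_id)
  rows <- lapply(pids, function(pid) {
    plog <- trial_logs[trial_logs$participant_id == pid, ]
    rp_post <- plog[plog$task == "reward_pairs" & plog$phase == "test" &
                      plog$day > 1, ]
    rp_pre <- plog[plog$task == "reward_pairs" & plog$phase == "test" &
                     plog$day == 1, ]
    uh_post <- plog[plog$task == "unrewarded_habit" & plog$phase == "test" &
                      plog$day > 1, ]
    uh_pre <- plog[plog$task == "unrewarded_habit" & plog$phase == "test" &
                     plog$day == 1, ]
    rp <- reward_pairs_scores_from_log(rp_post)
    uh <- unrewarded_scores_from_log(uh_post)
    rp0 <- if (nrow(rp_pre)) reward_pairs_scores_from_log(rp_pre) else
      list(choice = NA_real_, rt = NA_real_)
    uh0 <- if (nrow(uh_pre)) unrewarded_scores_from_log(uh_pre) else
      list(choice = NA_real_, rt = NA_real_)
    rat <- if (is.null(ratings)) list(reward_pairs = NA_real_, unrewarded = NA_real_)
    else rating_scores_from_table(ratings[ratings$participant_id == pid, ])
    data.frame(
      participant_id = pid,
      rp_choice = rp$choice, rp_rt = rp$rt, rp_rating = rat$reward_pairs,
      uh_choice = uh$choice, uh_rt = uh$rt, uh_rating = rat$unrewarded,
      rp_choice_training_effect = training_effect(rp0$choice, rp$choice, 2),
      rp_rt_training_effect = training_effect(rp0$rt, rp$rt, 2),
      uh_choice_training_effect = training_effect(uh0$choice, uh$choice, 2),
      uh_rt_training_effect = training_effect(uh0$rt, uh$rt, 2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
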