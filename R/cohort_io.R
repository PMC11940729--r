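# Cohort persistence: one gaze CSV per participant per task (columns
# participant_id, task, trial_index, condition, t, target_x, target_y,
# gaze_x, gaze_y, valid), one behavioral CSV per participant, and a JSON
# manifest. The same dialect serves as the ingestion format for real
# recordings. The condition column holds the trial's condition list as JSON
# so schedules can be reconstructed without the generator.

#' Write a cohort to CSV files
#'
#' @param cohort An `oc_cohort` (or list of `oc_session`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `<id>_<task>_gaze.csv` per gaze task,
#'   `<id>_behavior.csv`, and `manifest.json`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (s in cohort) {
    files <- character(0)
    for (task in names(s$gaze)) {
      rows <- lapply(seq_along(s$gaze[[task]]), function(i) {
        g <- s$gaze[[task]][[i]]
        tp <- target_position(g$trial, g$samples$t)
        cond <- g$trial$condition
        cond$trial_duration <- g$trial$duration
        data.frame(participant_id = s$participant_id, task = task,
                   trial_index = i,
                   condition = as.character(jsonlite::toJSON(
                     cond, auto_unbox = TRUE, digits = NA)),
                   t = g$samples$t, target_x = tp[, 1], target_y = tp[, 2],
                   gaze_x = g$samples$x, gaze_y = g$samples$y,
                   valid = g$samples$valid, stringsAsFactors = FALSE)
      })
      f <- file.path(dir, sprintf("%s_%s_gaze.csv", s$participant_id, task))
      utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
      files <- c(files, basename(f))
    }
    brows <- list()
    for (task in setdiff(names(s$behavior), "stroop")) {
      run <- s$behavior[[task]]
      brows[[task]] <- data.frame(
        participant_id = s$participant_id, task = task,
        trial_index = seq_len(nrow(run)),
        condition_or_length = run$length, correct = run$correct,
        rt = NA_real_, stringsAsFactors = FALSE)
    }
    st <- s$behavior$stroop
    brows$stroop <- data.frame(
      participant_id = s$participant_id, task = "stroop",
      trial_index = st$trial_index,
      condition_or_length = ifelse(st$congruent, "congruent", "incongruent"),
      correct = st$correct, rt = st$rt, stringsAsFactors = FALSE)
    bf <- file.path(dir, sprintf("%s_behavior.csv", s$participant_id))
    utils::write.csv(do.call(rbind, brows), bf, row.names = FALSE)
    manifest[[s$participant_id]] <-
      list(group = s$group, gaze_files = files, behavior_file = basename(bf))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

rebuild_trial <- function(task, cond, tdf) {
  dur <- if (!is.null(cond$trial_duration)) cond$trial_duration else
    max(tdf$t) + 1 / OCULOCOG_HZ
  if (task == "pursuit") {
    ev <- data.frame(onset = c(0, cond$sine_onset), x = 0, y = 0,
                     kind = c("fixation", "sine"), stringsAsFactors = FALSE)
    return(oc_trial(task, cond, ev, dur))
  }
  if (task == "memory_guided") {
    ev <- data.frame(
      onset = c(0, cond$flash_onset, cond$flash_onset + cond$flash_duration,
                cond$go_onset),
      x = c(0, cond$location, 0, 0), y = 0,
      kind = c("fixation", "step", "fixation", "step"),
      stringsAsFactors = FALSE)
    return(oc_trial(task, cond, ev, dur, timeout = 1.0))
  }
  if (task == "predictive") {
    onsets <- unlist(cond$step_onsets)
    cond$step_onsets <- onsets
    xs <- cond$first_sign * PREDICTIVE_AMP * rep_len(c(1, -1), 12)
    ev <- data.frame(onset = c(0, onsets), x = c(0, xs), y = 0,
                     kind = c("fixation", rep("step", 12)),
                     stringsAsFactors = FALSE)
    return(oc_trial(task, cond, ev, dur))
  }
  tt <- cond$target_onset
  pos <- dir_to_xy(cond$direction, PROANTI_ECC)
  ev <- data.frame(onset = c(0, tt), x = c(0, pos[1]), y = c(0, pos[2]),
                   kind = c("fixation", "step"), stringsAsFactors = FALSE)
  oc_trial(task, cond, ev, dur, timeout = 1.0)
}

#' Read a cohort from CSV files
#'
#' Reconstructs `oc_session` objects from the CSV dialect written by
#' [write_cohort_csv()] (or produced externally in the same layout).
#'
#' @param dir Directory containing the CSVs and `manifest.json`.
#' @return An `oc_cohort`.
#' @export
read_cohort_csv <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  sessions <- lapply(names(manifest), function(pid) {
    entry <- manifest[[pid]]
    gaze <- list()
    for (f in unlist(entry$gaze_files)) {
      df <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
      task <- df$task[1]
      gaze[[task]] <- lapply(split(df, df$trial_index), function(tdf) {
        cond <- jsonlite::fromJSON(tdf$condition[1], simplifyVector = TRUE)
        structure(list(
          trial = rebuild_trial(task, cond, tdf),
          samples = data.frame(t = tdf$t, x = tdf$gaze_x, y = tdf$gaze_y,
                               valid = tdf$valid),
          injected = list()), class = "oc_gaze_trial")
      })
    }
    bdf <- utils::read.csv(file.path(dir, entry$behavior_file),
                           stringsAsFactors = FALSE)
    behavior <- list()
    for (task in setdiff(unique(bdf$task), "stroop")) {
      rows <- bdf[bdf$task == task, , drop = FALSE]
      behavior[[task]] <- structure(
        data.frame(length = as.integer(rows$condition_or_length),
                   correct = as.logical(rows$correct)),
        class = c("oc_span_run", "data.frame"))
    }
    st <- bdf[bdf$task == "stroop", , drop = FALSE]
    behavior$stroop <- data.frame(
      trial_index = st$trial_index,
      congruent = st$condition_or_length == "congruent",
      correct = as.logical(st$correct), rt = as.numeric(st$rt))
    structure(list(participant_id = pid, group = entry$group,
                   gaze = gaze, behavior = behavior, truth = NULL),
              class = "oc_session")
  })
  structure(sessions, class = "oc_cohort")
}
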