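# Adaptive span-task logic and behavioral scoring: the 8 behavioral
# features (four span scores, Stroop accuracy and RT per congruency).

#' Run an adaptive span task
#'
#' Presents trials starting at list length 3. A correct trial increments the
#' length (terminating after a correct trial at `max_length`); an error
#' repeats the length. The run terminates after 3 consecutive errors. One
#' point is awarded per correct trial.
#'
#' @param responder Function of the list length returning `TRUE` (correct)
#'   or `FALSE`; typically a closure over an ability model or a recorded
#'   response sequence.
#' @param max_length Maximum list length (>= 3).
#' @return An object of class `"oc_span_run"`: `data.frame` with columns
#'   `length`, `correct`, plus attribute `terminated_early`.
#' @export
run_span_task <- function(responder, max_length = 9) {
  stopifnot(max_length >= 3)
  len <- 3L
  consec_err <- 0L
  lengths <- integer(0)
  corrects <- logical(0)
  terminated_early <- FALSE
  repeat {
    ok <- isTRUE(responder(len))
    lengths <- c(lengths, len)
    corrects <- c(corrects, ok)
    if (ok) {
      consec_err <- 0L
      if (len >= max_length) break
      len <- len + 1L
    } else {
      consec_err <- consec_err + 1L
      if (consec_err >= 3L) {
        terminated_early <- TRUE
        break
      }
    }
  }
  structure(data.frame(length = lengths, correct = corrects),
            terminated_early = terminated_early,
            class = c("oc_span_run", "data.frame"))
}

#' Score a span run
#'
#' @param run An `oc_span_run` (or any data frame with a `correct` column).
#' @return Points: the count of correct trials.
#' @export
score_span <- function(run) sum(run$correct)

#' Score the Stroop task
#'
#' Per congruency condition: accuracy is the proportion of correct trials;
#' RT is the mean reaction time over correct trials only (`NA` when no
#' correct trials exist in a condition).
#'
#' @param responses `data.frame` with columns `congruent` (logical),
#'   `correct` (logical), `rt` (seconds).
#' @return Named numeric vector: `stroop_congruent_accuracy`,
#'   `stroop_incongruent_accuracy`, `stroop_congruent_rt`,
#'   `stroop_incongruent_rt`.
#' @export
score_stroop <- function(responses) {
  stopifnot(all(c("congruent", "correct", "rt") %in% names(responses)))
  one <- function(cong) {
    rows <- responses[responses$congruent == cong, , drop = FALSE]
    if (nrow(rows) == 0) return(c(acc = NA_real_, rt = NA_real_))
    acc <- mean(rows$correct)
    rts <- rows$rt[rows$correct]
    c(acc = acc, rt = if (length(rts) > 0) mean(rts) else NA_real_)
  }
  con <- one(TRUE)
  inc <- one(FALSE)
  c(stroop_congruent_accuracy = con[["acc"]],
    stroop_incongruent_accuracy = inc[["acc"]],
    stroop_congruent_rt = con[["rt"]],
    stroop_incongruent_rt = inc[["rt"]])
}

#' Assemble the 8 behavioral features for a session
#'
#' @param session An `oc_session` containing all behavioral tasks.
#' @return Named numeric vector of length 8 in canonical order: the four
#'   span scores (forward/backward visuospatial, forward/backward digit)
#'   followed by the four Stroop values.
#' @export
assemble_behavior_features <- function(session) {
  b <- session$behavior
  missing <- setdiff(BEHAVIOR_TASKS, names(b))
  if (length(missing) > 0)
    stop("session is missing behavioral task(s): ",
         paste(missing, collapse = ", "))
  out <- c(span_fwd_visuospatial = score_span(b$span_fwd_vis),
           span_bwd_visuospatial = score_span(b$span_bwd_vis),
           span_fwd_digit = score_span(b$span_fwd_digit),
           span_bwd_digit = score_span(b$span_bwd_digit),
           score_stroop(b$stroop))
  stats::setNames(as.numeric(out), BEHAVIOR_FEATURE_NAMES)
}
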