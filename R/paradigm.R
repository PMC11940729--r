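# Sampling rate of the simulated tracker (Hz). All schedule timing is in
# seconds; traces are sampled on a 1/HZ grid.
OCULOCOG_HZ <- 60

#' Construct a single trial
#'
#' A trial bundles a task label, a task-specific condition, an ordered table
#' of target events (onset in seconds from trial start, position in degrees of
#' visual angle, event kind) and the trial duration. Trials are produced by
#' the `build_*_schedule()` constructors; this low-level constructor is
#' exported for testing and for loading externally recorded sessions.
#'
#' @param task Task name, e.g. `"prosaccade"`, `"pursuit"`.
#' @param condition Named list describing the condition (direction, frequency,
#'   congruency, ...).
#' @param events `data.frame` with columns `onset`, `x`, `y`, `kind`, ordered
#'   by onset.
#' @param duration Trial duration in seconds.
#' @param timeout Response timeout in seconds, or `NA` if none.
#' @param block Block index (rest-break structure only; does not affect
#'   analysis).
#' @return An object of class `"oc_trial"`.
#' @export
oc_trial <- function(task, condition, events, duration, timeout = NA_real_,
                     block = 1L) {
  stopifnot(is.data.frame(events),
            all(c("onset", "x", "y", "kind") %in% names(events)))
  if (is.unsorted(events$onset)) stop("trial events must be ordered by onset")
  if (any(events$onset < 0)) stop("event onsets must be >= 0")
  structure(list(task = task, condition = condition, events = events,
                 duration = duration, timeout = timeout, block = block),
            class = "oc_trial")
}

new_schedule <- function(task, trials, seed) {
  structure(list(task = task, trials = trials, seed = as.integer(seed)),
            class = "oc_schedule")
}

#' @export
print.oc_schedule <- function(x, ...) {
  cat(sprintf("<oc_schedule> task=%s trials=%d seed=%d\n",
              x$task, length(x$trials), x$seed))
  invisible(x)
}

#' @export
length.oc_schedule <- function(x) length(x$trials)

# Target eccentricity of the pro/anti-saccade circles (degrees).
PROANTI_ECC <- 9.7
# Pursuit sine amplitude: 10 degrees either side of center.
PURSUIT_AMP <- 10
# Predictive-saccade target locations: +/- 10 degrees horizontal.
PREDICTIVE_AMP <- 10

#' Build the pro-/anti-saccade task schedule
#'
#' 64 formal trials: 4 target positions (plus/minus 9.7 degrees horizontal
#' and vertical) crossed with pro vs anti instruction, 8 repetitions each,
#' randomized order, split over 2 blocks. Central fixation lasts a uniform
#' 1.0--1.5 s; the response window is 1.0 s after target onset.
#'
#' @param seed Integer seed; the schedule is bitwise-reproducible under it.
#' @return An `oc_schedule` with 64 trials.
#' @export
build_prosaccade_schedule <- function(seed = 0L) {
  withr_seed(seed, {
    dirs <- c("right", "left", "up", "down")
    grid <- expand.grid(dir = dirs, type = c("pro", "anti"),
                        rep = seq_len(8), stringsAsFactors = FALSE)
    ord <- sample.int(nrow(grid))
    grid <- grid[ord, , drop = FALSE]
    fixdur <- stats::runif(nrow(grid), 1.0, 1.5)
    trials <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      pos <- dir_to_xy(grid$dir[i], PROANTI_ECC)
      ev <- data.frame(
        onset = c(0, fixdur[i]),
        x = c(0, pos[1]), y = c(0, pos[2]),
        kind = c("fixation", "step"),
        stringsAsFactors = FALSE)
      trials[[i]] <- oc_trial(
        task = "prosaccade",
        condition = list(direction = grid$dir[i], type = grid$type[i],
                         target_onset = fixdur[i]),
        events = ev, duration = fixdur[i] + 1.0, timeout = 1.0,
        block = if (i <= nrow(grid) / 2) 1L else 2L)
    }
    new_schedule("prosaccade", trials, seed)
  })
}

#' Build the smooth pursuit task schedule
#'
#' 8 formal trials: horizontal and vertical motion crossed with 0.25 Hz and
#' 0.4 Hz sinusoidal oscillation, 2 repetitions each. The target oscillates
#' with 10 degree amplitude either side of center (20 degrees total travel),
#' starting at center and moving in the positive direction. Each trial has a
#' 1.2 s pre-trial central fixation followed by 10 s of pursuit.
#'
#' @inheritParams build_prosaccade_schedule
#' @return An `oc_schedule` with 8 trials.
#' @export
build_pursuit_schedule <- function(seed = 0L) {
  withr_seed(seed, {
    grid <- expand.grid(axis = c("h", "v"), freq = c(0.25, 0.4),
                        rep = 1:2, stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    fix <- 1.2
    dur <- 10
    trials <- lapply(seq_len(nrow(grid)), function(i) {
      ev <- data.frame(onset = c(0, fix), x = 0, y = 0,
                       kind = c("fixation", "sine"),
                       stringsAsFactors = FALSE)
      oc_trial("pursuit",
               condition = list(axis = grid$axis[i], freq = grid$freq[i],
                                amplitude = PURSUIT_AMP, sine_onset = fix),
               events = ev, duration = fix + dur)
    })
    new_schedule("pursuit", trials, seed)
  })
}

#' Build the memory-guided saccade task schedule
#'
#' 60 formal trials: 6 flash locations (plus/minus 5, 10, 15 degrees
#' horizontal), 10 repetitions each, over 2 blocks. After a 1.0--1.5 s central
#' fixation, the target flashes for 100 ms; the fixation cross stays on for a
#' further uniform 4.5--5.0 s delay, then disappears (go signal); the response
#' window is 1.0 s.
#'
#' @inheritParams build_prosaccade_schedule
#' @return An `oc_schedule` with 60 trials.
#' @export
build_memory_guided_schedule <- function(seed = 0L) {
  withr_seed(seed, {
    locs <- c(-15, -10, -5, 5, 10, 15)
    grid <- expand.grid(loc = locs, rep = seq_len(10))
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    fixdur <- stats::runif(nrow(grid), 1.0, 1.5)
    delay <- stats::runif(nrow(grid), 4.5, 5.0)
    trials <- lapply(seq_len(nrow(grid)), function(i) {
      t_flash <- fixdur[i]
      t_go <- t_flash + 0.1 + delay[i]
      ev <- data.frame(
        onset = c(0, t_flash, t_flash + 0.1, t_go),
        x = c(0, grid$loc[i], 0, 0), y = 0,
        kind = c("fixation", "step", "fixation", "step"),
        stringsAsFactors = FALSE)
      oc_trial("memory_guided",
               condition = list(location = grid$loc[i],
                                eccentricity = abs(grid$loc[i]),
                                flash_onset = t_flash,
                                flash_duration = 0.1, go_onset = t_go),
               events = ev, duration = t_go + 1.0, timeout = 1.0,
               block = if (i <= nrow(grid) / 2) 1L else 2L)
    })
    new_schedule("memory_guided", trials, seed)
  })
}

#' Build the predictive saccade task schedule
#'
#' 25 formal trials: 5 alternation rates (0.66, 0.8, 1, 1.33, 2 Hz, i.e.
#' inter-step intervals of 1.5, 1.25, 1.0, 0.75 and 0.5 s), 5 repetitions
#' each over 5 blocks. In each trial the target makes 12 steps alternating
#' between plus/minus 10 degrees horizontal; the first step direction is
#' randomized per trial.
#'
#' @inheritParams build_prosaccade_schedule
#' @return An `oc_schedule` with 25 trials.
#' @export
build_predictive_schedule <- function(seed = 0L) {
  withr_seed(seed, {
    rates <- c(0.66, 0.8, 1, 1.33, 2)
    isis <- c(1.5, 1.25, 1.0, 0.75, 0.5)
    grid <- expand.grid(rate_i = seq_along(rates), rep = seq_len(5))
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    fixdur <- stats::runif(nrow(grid), 1.0, 1.5)
    first_sign <- sample(c(-1, 1), nrow(grid), replace = TRUE)
    trials <- lapply(seq_len(nrow(grid)), function(i) {
      isi <- isis[grid$rate_i[i]]
      onsets <- fixdur[i] + isi * (0:11)
      # step 1 lands at first_sign * 10 degrees, then alternates
      xs <- first_sign[i] * PREDICTIVE_AMP * rep_len(c(1, -1), 12)
      ev <- data.frame(onset = c(0, onsets),
                       x = c(0, xs), y = 0,
                       kind = c("fixation", rep("step", 12)),
                       stringsAsFactors = FALSE)
      oc_trial("predictive",
               condition = list(rate = rates[grid$rate_i[i]], isi = isi,
                                first_sign = first_sign[i],
                                step_onsets = onsets),
               events = ev, duration = onsets[12] + isi,
               block = grid$rate_i[i])
    })
    new_schedule("predictive", trials, seed)
  })
}

#' Build the Stroop task schedule
#'
#' 90 formal trials: 3 color words crossed with 3 ink colors (9 stimulus
#' levels), 10 repetitions each, randomized order. A trial is congruent when
#' the word matches its ink color (30 congruent, 60 incongruent trials).
#'
#' @inheritParams build_prosaccade_schedule
#' @return An `oc_schedule` with 90 trials.
#' @export
build_stroop_schedule <- function(seed = 0L) {
  withr_seed(seed, {
    cols <- c("red", "green", "blue")
    grid <- expand.grid(word = cols, ink = cols, rep = seq_len(10),
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    trials <- lapply(seq_len(nrow(grid)), function(i) {
      ev <- data.frame(onset = 0, x = 0, y = 0, kind = "stroop_stimulus",
                       stringsAsFactors = FALSE)
      oc_trial("stroop",
               condition = list(word = grid$word[i], ink = grid$ink[i],
                                congruent = grid$word[i] == grid$ink[i]),
               events = ev, duration = 3.0)
    })
    new_schedule("stroop", trials, seed)
  })
}

#' Closed-form target position at time t
#'
#' Shared by the gaze simulator and the pursuit delay estimator: the target
#' trajectory is piecewise constant for step tasks (right-continuous square
#' wave) and `A * sin(2 pi f (t - onset))` along the motion axis for pursuit.
#'
#' @param trial An `oc_trial`.
#' @param t Time in seconds from trial start (vectorized).
#' @return A matrix with columns `x`, `y` (degrees).
#' @export
target_position <- function(trial, t) {
  if (any(t < 0 | t > trial$duration + 1e-9))
    stop("t outside trial duration")
  if (trial$task == "pursuit") {
    cond <- trial$condition
    ph <- pmax(t - cond$sine_onset, 0)
    s <- cond$amplitude * sin(2 * pi * cond$freq * ph)
    out <- cbind(x = if (cond$axis == "h") s else 0 * s,
                 y = if (cond$axis == "v") s else 0 * s)
    return(out)
  }
  ev <- trial$events
  idx <- findInterval(t + 1e-12, ev$onset)
  idx[idx < 1] <- 1L
  cbind(x = ev$x[idx], y = ev$y[idx])
}

#' Serialize / deserialize a schedule to JSON
#'
#' @param schedule An `oc_schedule`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `schedule_to_json`: the path (invisibly) or a JSON string.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  doc <- list(task = schedule$task, seed = schedule$seed,
              trials = lapply(schedule$trials, function(tr) {
                list(task = tr$task, condition = tr$condition,
                     duration = tr$duration, timeout = tr$timeout,
                     block = tr$block, events = tr$events)
              }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so schedule building never perturbs simulations.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

dir_to_xy <- function(dir, ecc) {
  switch(dir,
         right = c(ecc, 0), left = c(-ecc, 0),
         up = c(0, ecc), down = c(0, -ecc),
         stop("unknown direction: ", dir))
}

# Mirror position for anti-saccade instruction.
mirror_xy <- function(xy) -xy
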