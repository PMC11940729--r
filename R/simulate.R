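# Synthetic 60 Hz gaze generator. Saccades follow a minimum-jerk displacement
# profile with a main-sequence duration rule; pursuit is a delayed, gain-
# scaled copy of the target plus Poisson catch-up saccades that close the
# accumulated positional error; blinks appear as invalid gaps.

# Minimum-jerk normalized displacement, s in [0, 1].
minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

# Main-sequence duration rule: ~20 ms base + 2 ms per degree of amplitude,
# never shorter than 2 samples at 60 Hz.
saccade_duration <- function(amplitude) {
  pmax(2 / OCULOCOG_HZ, 0.02 + 0.002 * amplitude)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 100003) %%
               2147483587) + 1L
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

# Overlay a saccadic movement onto a sample-wise position matrix: from the
# current planned position at t_start, a minimum-jerk transition to `to`.
apply_movement <- function(pos, t, t_start, to) {
  i0 <- findInterval(t_start, t)
  if (i0 < 1) i0 <- 1L
  from <- pos[i0, ]
  amp <- sqrt(sum((to - from)^2))
  D <- saccade_duration(amp)
  sel <- t >= t_start
  s <- pmin((t[sel] - t_start) / D, 1)
  w <- minjerk(s)
  pos[sel, 1] <- from[1] + (to[1] - from[1]) * w
  pos[sel, 2] <- from[2] + (to[2] - from[2]) * w
  pos
}

#' Simulate one 60 Hz gaze trial
#'
#' Generates the gaze trace for a single trial of one of the four oculomotor
#' tasks under a phenotype profile. Fixation is the fixated location plus
#' white noise; saccades are latency draws followed by minimum-jerk
#' displacements whose duration follows a main-sequence rule; anti-saccade
#' trials err toward the cue (then correct) with probability
#' `anti_error_rate`; pursuit is the target delayed by `pursuit_delay` and
#' scaled by `pursuit_gain` plus catch-up saccades at `catchup_rate` closing
#' the accumulated positional error; memory-guided and predictive trials
#' follow their response rules. Blinks are inserted as invalid gaps.
#'
#' The returned object carries an `injected` list (true latencies, catch-up
#' amplitudes, response flags) retained for parameter-recovery testing.
#'
#' @param trial An `oc_trial` from a gaze task.
#' @param profile An `oc_profile`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [generate_cohort()]).
#' @return An object of class `"oc_gaze_trial"`: list with `trial`,
#'   `samples` (`data.frame` with `t`, `x`, `y`, `valid`) and `injected`.
#' @export
simulate_gaze_trial <- function(trial, profile, seed = NULL) {
  if (!inherits(trial, "oc_trial")) stop("trial must be an oc_trial")
  if (!trial$task %in% c("prosaccade", "pursuit", "memory_guided",
                         "predictive"))
    stop("not a gaze task: ", trial$task)
  if (!is.null(seed)) return(withr_seed(seed,
    simulate_gaze_trial(trial, profile, seed = NULL)))

  n <- floor(trial$duration * OCULOCOG_HZ) + 1L
  t <- (seq_len(n) - 1) / OCULOCOG_HZ
  injected <- list()

  if (trial$task == "pursuit") {
    cond <- trial$condition
    tgt_ax <- function(u) {
      ph <- pmax(u - cond$sine_onset, 0)
      cond$amplitude * sin(2 * pi * cond$freq * ph)
    }
    smooth <- profile$pursuit_gain * tgt_ax(t - profile$pursuit_delay)
    smooth[t < cond$sine_onset] <- 0
    # catch-up saccades: at each event, jump the offset to the current
    # positional error between target and the smooth component
    pursuit_span <- trial$duration - cond$sine_onset
    n_cu <- stats::rpois(1, profile$catchup_rate * pursuit_span)
    cu_t <- sort(stats::runif(n_cu, cond$sine_onset + 0.3, trial$duration))
    offs <- rep(0, n)
    cur <- 0
    cu_amp <- cu_used <- numeric(0)
    for (tc in cu_t) {
      target_off <- tgt_ax(tc) - profile$pursuit_gain *
        tgt_ax(tc - profile$pursuit_delay)
      amp <- abs(target_off - cur)
      if (amp < 0.25) next  # no catch-up needed
      D <- saccade_duration(amp)
      sel <- t >= tc
      s <- pmin((t[sel] - tc) / D, 1)
      offs[sel] <- cur + (target_off - cur) * minjerk(s)
      cu_amp <- c(cu_amp, amp)
      cu_used <- c(cu_used, tc)
      cur <- target_off
    }
    ax <- smooth + offs
    pos <- cbind(if (cond$axis == "h") ax else 0 * ax,
                 if (cond$axis == "v") ax else 0 * ax)
    injected$catchup_amplitudes <- cu_amp
    injected$catchup_times <- cu_used
  } else if (trial$task == "prosaccade") {
    cond <- trial$condition
    tt <- trial$events$onset[trial$events$kind == "step"][1]
    cue <- dir_to_xy(cond$direction, PROANTI_ECC)
    instructed <- if (cond$type == "pro") cue else -cue
    lat <- rtrunc_norm(1, profile$saccade_latency_mean,
                       profile$saccade_latency_sd, lower = 0.08, upper = 0.95)
    gain <- rtrunc_norm(1, profile$saccade_gain_mean, profile$saccade_gain_sd,
                        lower = 0.2, upper = 1.5)
    pos <- matrix(0, n, 2)
    err <- cond$type == "anti" && stats::runif(1) < profile$anti_error_rate
    if (err) {
      g_err <- rtrunc_norm(1, profile$saccade_gain_mean,
                           profile$saccade_gain_sd, lower = 0.2, upper = 1.5)
      pos <- apply_movement(pos, t, tt + lat, cue * g_err)
      t_corr <- tt + lat + saccade_duration(PROANTI_ECC * g_err) +
        stats::runif(1, 0.10, 0.20)
      pos <- apply_movement(pos, t, t_corr, instructed * gain)
    } else {
      pos <- apply_movement(pos, t, tt + lat, instructed * gain)
    }
    injected$latency <- lat
    injected$gain <- gain
    injected$error_first <- err
  } else if (trial$task == "memory_guided") {
    cond <- trial$condition
    pos <- matrix(0, n, 2)
    fail <- stats::runif(1) < profile$memory_fail_rate
    if (!fail) {
      lat <- rtrunc_norm(1, profile$saccade_latency_mean,
                         profile$saccade_latency_sd, lower = 0.08,
                         upper = 0.95)
      gain <- rtrunc_norm(1, profile$memory_gain_mean, profile$memory_gain_sd,
                          lower = 0.2, upper = 1.5)
      pos <- apply_movement(pos, t, cond$go_onset + lat,
                            c(cond$location * gain, 0))
      injected$latency <- lat
      injected$gain <- gain
    }
    injected$responded <- !fail
  } else {  # predictive
    cond <- trial$condition
    onsets <- cond$step_onsets
    xs <- cond$first_sign * PREDICTIVE_AMP * rep_len(c(1, -1), 12)
    pos <- matrix(0, n, 2)
    prev_land <- 0
    prev_end <- 0
    lat_k <- amp_k <- rep(NA_real_, 12)
    for (k in 1:12) {
      anticip <- k > 1 && stats::runif(1) < profile$predictive_anticipation
      lat <- if (anticip) {
        -rtrunc_norm(1, profile$predictive_latency_mean,
                     profile$predictive_latency_sd, lower = 0.02,
                     upper = 0.24)
      } else {
        rtrunc_norm(1, profile$saccade_latency_mean,
                    profile$predictive_latency_sd, lower = 0.08, upper = 0.45)
      }
      gain <- rtrunc_norm(1, profile$saccade_gain_mean,
                          profile$saccade_gain_sd, lower = 0.2, upper = 1.5)
      t_start <- max(onsets[k] + lat, prev_end + 1 / OCULOCOG_HZ)
      landing <- prev_land + (xs[k] - prev_land) * gain
      amp <- abs(landing - prev_land)
      pos <- apply_movement(pos, t, t_start, c(landing, 0))
      lat_k[k] <- t_start - onsets[k]
      amp_k[k] <- amp
      prev_land <- landing
      prev_end <- t_start + saccade_duration(amp)
    }
    injected$step_latencies <- lat_k
    injected$step_amplitudes <- amp_k
  }

  if (profile$fixation_noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(2 * n, 0, profile$fixation_noise_sd),
                        n, 2)
  valid <- rep(TRUE, n)
  if (profile$blink_rate > 0) {
    n_bl <- stats::rpois(1, profile$blink_rate * trial$duration / 60)
    if (n_bl > 0) {
      bt <- stats::runif(n_bl, 0, trial$duration)
      bd <- stats::runif(n_bl, 0.1, 0.2)
      for (j in seq_len(n_bl)) valid[t >= bt[j] & t <= bt[j] + bd[j]] <- FALSE
    }
  }
  pos[!valid, ] <- NA_real_

  structure(list(trial = trial,
                 samples = data.frame(t = t, x = pos[, 1], y = pos[, 2],
                                      valid = valid),
                 injected = injected),
            class = "oc_gaze_trial")
}

#' Simulate the behavioral task battery for one participant
#'
#' Runs the four adaptive span tasks (forward/backward visuospatial and digit
#' span) with a logistic ability model -- a trial at list length L is correct
#' with probability `plogis((ability - L)/scale) * (1 - span_lapse)` -- and
#' the 90-trial Stroop schedule, where each response is correct with the
#' congruency's accuracy and the RT is the base RT plus the interference cost
#' (incongruent only) plus noise.
#'
#' @param profile An `oc_profile`.
#' @param seed Optional integer seed (otherwise the current RNG stream).
#' @param span_scale Logistic scale of the span psychometric function (items).
#' @param max_length_digit,max_length_visuospatial Span ceilings.
#' @return Named list with elements `span_fwd_vis`, `span_bwd_vis`,
#'   `span_fwd_digit`, `span_bwd_digit` (each an `oc_span_run`) and `stroop`
#'   (`data.frame` with `congruent`, `correct`, `rt`).
#' @export
simulate_behavior <- function(profile, seed = NULL, span_scale = 0.6,
                              max_length_digit = 9,
                              max_length_visuospatial = 8) {
  if (!is.null(seed)) return(withr_seed(seed,
    simulate_behavior(profile, seed = NULL, span_scale = span_scale,
                      max_length_digit = max_length_digit,
                      max_length_visuospatial = max_length_visuospatial)))
  abilities <- c(
    span_fwd_vis = profile$span_ability,
    span_bwd_vis = profile$span_ability - profile$span_bwd_deficit,
    span_fwd_digit = profile$span_ability,
    span_bwd_digit = profile$span_ability - profile$span_bwd_deficit -
      profile$span_bwd_digit_extra)
  maxlen <- c(span_fwd_vis = max_length_visuospatial,
              span_bwd_vis = max_length_visuospatial,
              span_fwd_digit = max_length_digit,
              span_bwd_digit = max_length_digit)
  out <- lapply(names(abilities), function(nm) {
    ability <- abilities[[nm]]
    responder <- function(len) {
      p <- stats::plogis((ability - len) / span_scale) *
        (1 - profile$span_lapse)
      stats::runif(1) < p
    }
    run_span_task(responder, max_length = maxlen[[nm]])
  })
  names(out) <- names(abilities)

  sched <- build_stroop_schedule(seed = sample.int(1e6, 1))
  cong <- vapply(sched$trials, function(tr) tr$condition$congruent, logical(1))
  err <- ifelse(cong, profile$stroop_error_rate_congruent,
                profile$stroop_error_rate_incongruent)
  correct <- stats::runif(length(cong)) > err
  rt <- profile$stroop_rt_base +
    ifelse(cong, 0, profile$stroop_interference) +
    stats::rnorm(length(cong), 0, profile$stroop_rt_sd)
  rt <- pmax(rt, 0.15)
  out$stroop <- data.frame(trial_index = seq_along(cong), congruent = cong,
                           correct = correct, rt = rt)
  out
}

GAZE_TASKS <- c("prosaccade", "pursuit", "memory_guided", "predictive")
BEHAVIOR_TASKS <- c("span_fwd_vis", "span_bwd_vis", "span_fwd_digit",
                    "span_bwd_digit", "stroop")

#' Simulate a complete participant session
#'
#' @param participant_id Participant identifier.
#' @param group Group label.
#' @param profile Individual `oc_profile`.
#' @param seed Integer seed driving all of the session's randomness.
#' @return An object of class `"oc_session"`: list with `participant_id`,
#'   `group`, `gaze` (task -> list of `oc_gaze_trial`), `behavior` (see
#'   [simulate_behavior()]) and `truth` (the profile used).
#' @export
simulate_session <- function(participant_id, group, profile, seed) {
  withr_seed(seed, {
    builders <- list(prosaccade = build_prosaccade_schedule,
                     pursuit = build_pursuit_schedule,
                     memory_guided = build_memory_guided_schedule,
                     predictive = build_predictive_schedule)
    gaze <- lapply(builders, function(b) {
      sched <- b(seed = sample.int(1e6, 1))
      lapply(sched$trials, simulate_gaze_trial, profile = profile)
    })
    behavior <- simulate_behavior(profile)
    structure(list(participant_id = participant_id, group = group,
                   gaze = gaze, behavior = behavior, truth = profile),
              class = "oc_session")
  })
}

#' @export
print.oc_session <- function(x, ...) {
  cat(sprintf("<oc_session> %s (%s): %d gaze tasks, %d behavioral tasks\n",
              x$participant_id, x$group, length(x$gaze), length(x$behavior)))
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' Simulates `n_young + n_control + n_mci` complete participant sessions.
#' Each participant's parameters are an individual draw around their group's
#' profile (see [draw_individual_profile()]); all randomness derives from
#' `seed`, so the same seed reproduces the cohort byte-for-byte. The default
#' cohort composition (31/57/40) mirrors a valid sample of 128 participants.
#'
#' @param n_young,n_control,n_mci Group sizes.
#' @param seed Integer seed.
#' @param profiles Optional named list of group profiles (defaults to
#'   [default_profiles()]).
#' @param jitter_cv Between-subject coefficient of variation.
#' @return An object of class `"oc_cohort"`: list of `oc_session`.
#' @export
generate_cohort <- function(n_young = 31, n_control = 57, n_mci = 40,
                            seed = 1, profiles = default_profiles(),
                            jitter_cv = PROFILE_JITTER_CV) {
  stopifnot(n_young >= 0, n_control >= 0, n_mci >= 0)
  groups <- rep(c("young", "control", "mci"),
                times = c(n_young, n_control, n_mci))
  sessions <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    pseed <- derive_seed(seed, i)
    indiv <- withr_seed(pseed,
      draw_individual_profile(profiles[[g]], cv = jitter_cv))
    sessions[[i]] <- simulate_session(
      participant_id = sprintf("%s_%03d", g, sum(groups[1:i] == g)),
      group = g, profile = indiv, seed = derive_seed(pseed, 7L))
  }
  structure(sessions, class = "oc_cohort")
}

#' @export
print.oc_cohort <- function(x, ...) {
  grp <- table(vapply(x, function(s) s$group, character(1)))
  cat("<oc_cohort>", length(x), "sessions:",
      paste(names(grp), as.integer(grp), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
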