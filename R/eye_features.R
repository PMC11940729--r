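# The 31 eye-movement features, computed per task from detected events and
# clean traces. Canonical order (pro/anti 10, pursuit 12, memory-guided 5,
# predictive 4) is fixed package-wide; see EYE_FEATURE_NAMES.

EYE_FEATURE_NAMES <- c(
  "pa_fixation_dispersion", "pa_mean_accuracy", "pa_pro_accuracy",
  "pa_anti_accuracy", "pa_mean_latency", "pa_pro_latency",
  "pa_anti_latency", "pa_mean_gain", "pa_pro_gain", "pa_anti_gain",
  "sp_fixation_dispersion", "sp_saccade_compensation", "sp_mean_variance",
  "sp_variance_v_025", "sp_variance_v_04", "sp_variance_h_025",
  "sp_variance_h_04", "sp_mean_delay", "sp_delay_v_025", "sp_delay_v_04",
  "sp_delay_h_025", "sp_delay_h_04",
  "mg_fixation_dispersion", "mg_mean_gain", "mg_gain_5", "mg_gain_10",
  "mg_gain_15",
  "ps_fixation_dispersion", "ps_mean_variance", "ps_mean_latency",
  "ps_mean_gain")

BEHAVIOR_FEATURE_NAMES <- c(
  "span_fwd_visuospatial", "span_bwd_visuospatial", "span_fwd_digit",
  "span_bwd_digit", "stroop_congruent_accuracy",
  "stroop_incongruent_accuracy", "stroop_congruent_rt",
  "stroop_incongruent_rt")

ALL_FEATURE_NAMES <- c(EYE_FEATURE_NAMES, BEHAVIOR_FEATURE_NAMES)

# Minimum amplitude for a saccade to count as a task response (degrees):
# separates responses from fixational noise at 60 Hz.
PRIMARY_SACCADE_MIN_AMP <- 2

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

prep_task <- function(gtrials) {
  lapply(gtrials, function(g) {
    ct <- preprocess(g)
    list(trace = ct, saccades = detect_saccades(ct))
  })
}

#' Pro-/anti-saccade task features (10 values)
#'
#' Per trial, the primary saccade is the first detected event after target
#' onset with amplitude >= 2 degrees. A trial is correct when the primary
#' saccade's direction has positive projection on the instructed direction
#' (toward the cue for pro, opposite for anti) and its onset is within the
#' 1 s response window. Accuracy is correct/usable trials per condition;
#' latency is the mean onset minus target onset over correct trials; gain is
#' the mean absolute projection of the onset-to-landing displacement on the
#' instructed axis divided by the 9.7 degree eccentricity. `mean_*` features
#' average the pro and anti condition values; fixation dispersion is the RMS
#' dispersion of pre-target fixation.
#'
#' @param gtrials List of `oc_gaze_trial` from the pro/anti task.
#' @return Named numeric vector of the task's 10 features.
#' @export
proanti_features <- function(gtrials) {
  per <- data.frame(type = character(0), correct = logical(0),
                    latency = numeric(0), gain = numeric(0),
                    disp = numeric(0))
  for (g in gtrials) {
    ct <- preprocess(g)
    if (!ct$usable) next
    sac <- detect_saccades(ct)
    tr <- g$trial
    tt <- tr$events$onset[tr$events$kind == "step"][1]
    cue <- dir_to_xy(tr$condition$direction, PROANTI_ECC)
    instr_u <- (if (tr$condition$type == "pro") cue else -cue) / PROANTI_ECC
    disp <- window_dispersion(ct, sac, 0, tt)
    prim <- sac[sac$onset > tt & sac$amplitude >= PRIMARY_SACCADE_MIN_AMP, ,
                drop = FALSE]
    if (nrow(prim) == 0) {
      per <- rbind(per, data.frame(type = tr$condition$type, correct = FALSE,
                                   latency = NA_real_, gain = NA_real_,
                                   disp = disp))
      next
    }
    p1 <- prim[1, ]
    proj_dir <- p1$dx * instr_u[1] + p1$dy * instr_u[2]
    ok <- proj_dir > 0 && (p1$onset - tt) <= tr$timeout
    land <- landing_pos(ct, p1)
    take <- takeoff_pos(ct, p1)
    dxy <- land - take
    gain <- abs(dxy[1] * instr_u[1] + dxy[2] * instr_u[2]) / PROANTI_ECC
    per <- rbind(per, data.frame(type = tr$condition$type, correct = ok,
                                 latency = if (ok) p1$onset - tt else NA,
                                 gain = if (ok) gain else NA, disp = disp))
  }
  vals <- c(pa_fixation_dispersion = mean_or_na(per$disp[!is.na(per$disp)]))
  acc <- lat <- gn <- c(pro = NA_real_, anti = NA_real_)
  for (ty in c("pro", "anti")) {
    rows <- per[per$type == ty, , drop = FALSE]
    if (nrow(rows) == 0) next
    acc[ty] <- mean(rows$correct)
    lat[ty] <- mean_or_na(rows$latency[rows$correct & !is.na(rows$latency)])
    gn[ty] <- mean_or_na(rows$gain[rows$correct & !is.na(rows$gain)])
  }
  c(vals,
    pa_mean_accuracy = mean(acc), pa_pro_accuracy = acc[["pro"]],
    pa_anti_accuracy = acc[["anti"]],
    pa_mean_latency = mean(lat), pa_pro_latency = lat[["pro"]],
    pa_anti_latency = lat[["anti"]],
    pa_mean_gain = mean(gn), pa_pro_gain = gn[["pro"]],
    pa_anti_gain = gn[["anti"]])
}

# Delay (s) maximizing the cross-correlation between the de-saccaded gaze
# signal and the target along the motion axis, on a 1-sample lag grid.
estimate_pursuit_delay <- function(trace, saccades, trial, max_lag = 0.5) {
  cond <- trial$condition
  ax_sig <- if (cond$axis == "h") trace$x else trace$y
  # remove saccadic intervals and interpolate across them
  keep <- !trace$excluded
  if (nrow(saccades) > 0)
    for (k in seq_len(nrow(saccades)))
      keep[saccades$onset_i[k]:saccades$offset_i[k]] <- FALSE
  in_pursuit <- trace$t >= cond$sine_onset
  if (sum(keep & in_pursuit) < 20) return(list(delay = NA_real_,
                                               variance = NA_real_))
  sig <- ax_sig
  if (any(!keep) && sum(keep) >= 2)
    sig[!keep] <- stats::approx(trace$t[keep], ax_sig[keep],
                                xout = trace$t[!keep], rule = 2)$y
  tgt <- function(u) {
    ph <- pmax(u - cond$sine_onset, 0)
    cond$amplitude * sin(2 * pi * cond$freq * ph)
  }
  lags <- seq(0, max_lag, by = 1 / OCULOCOG_HZ)
  sel <- in_pursuit & trace$t >= cond$sine_onset + max_lag
  g <- sig[sel]
  ts <- trace$t[sel]
  if (stats::sd(g) < 1e-9) return(list(delay = NA_real_,
                                       variance = NA_real_))
  cors <- vapply(lags, function(L) stats::cor(g, tgt(ts - L)), numeric(1))
  delay <- lags[which.max(cors)]
  err <- (sig - tgt(trace$t - delay))[in_pursuit]
  list(delay = delay, variance = stats::var(err))
}

#' Smooth pursuit task features (12 values)
#'
#' Per trial, after removing saccadic intervals from the gaze signal and
#' interpolating across them: the delay is the lag in [0, 0.5] s (1-sample
#' grid) maximizing the cross-correlation between gaze and target along the
#' motion axis; the variance is the variance of the positional error between
#' the de-saccaded gaze and the delay-shifted target (deg^2). Per-condition
#' values average the 2 repetitions; `mean_delay` and `mean_variance`
#' average all trials. Saccade compensation is the summed catch-up saccade
#' amplitude along the motion axis divided by the total target path length,
#' averaged over trials. Fixation dispersion comes from the pre-trial
#' fixation.
#'
#' @param gtrials List of `oc_gaze_trial` from the pursuit task.
#' @return Named numeric vector of the task's 12 features.
#' @export
pursuit_features <- function(gtrials) {
  rows <- data.frame(axis = character(0), freq = numeric(0),
                     delay = numeric(0), variance = numeric(0),
                     comp = numeric(0), disp = numeric(0))
  for (g in gtrials) {
    ct <- preprocess(g)
    if (!ct$usable) next
    sac <- detect_saccades(ct)
    cond <- g$trial$condition
    est <- estimate_pursuit_delay(ct, sac, g$trial)
    disp <- window_dispersion(ct, sac, 0, cond$sine_onset)
    # catch-up saccades: events during pursuit; amplitude projected on axis
    dur <- g$trial$duration - cond$sine_onset
    path_len <- 4 * cond$amplitude * cond$freq * dur
    in_p <- sac[sac$onset >= cond$sine_onset, , drop = FALSE]
    ax_amp <- if (cond$axis == "h") abs(in_p$amplitude * in_p$dx) else
      abs(in_p$amplitude * in_p$dy)
    rows <- rbind(rows, data.frame(
      axis = cond$axis, freq = cond$freq, delay = est$delay,
      variance = est$variance, comp = sum(ax_amp) / path_len, disp = disp))
  }
  cell <- function(ax, fr, what) {
    v <- rows[rows$axis == ax & rows$freq == fr, what]
    mean_or_na(v[!is.na(v)])
  }
  c(sp_fixation_dispersion = mean_or_na(rows$disp[!is.na(rows$disp)]),
    sp_saccade_compensation = mean_or_na(rows$comp[!is.na(rows$comp)]),
    sp_mean_variance = mean_or_na(rows$variance[!is.na(rows$variance)]),
    sp_variance_v_025 = cell("v", 0.25, "variance"),
    sp_variance_v_04 = cell("v", 0.4, "variance"),
    sp_variance_h_025 = cell("h", 0.25, "variance"),
    sp_variance_h_04 = cell("h", 0.4, "variance"),
    sp_mean_delay = mean_or_na(rows$delay[!is.na(rows$delay)]),
    sp_delay_v_025 = cell("v", 0.25, "delay"),
    sp_delay_v_04 = cell("v", 0.4, "delay"),
    sp_delay_h_025 = cell("h", 0.25, "delay"),
    sp_delay_h_04 = cell("h", 0.4, "delay"))
}

#' Memory-guided saccade task features (5 values)
#'
#' Per trial, the response saccade is the first event with amplitude >= 2
#' degrees within the 1 s window after the central cross offset (the go
#' signal); gain is its onset-to-landing displacement projected on the
#' target direction divided by the eccentricity. `gain_5/10/15` pool both
#' signs of each eccentricity; `mean_gain` averages the three eccentricity
#' gains. Trials with no response saccade are excluded from gain averages.
#' Fixation dispersion is computed over the memory delay period.
#'
#' @param gtrials List of `oc_gaze_trial` from the memory-guided task.
#' @return Named numeric vector of the task's 5 features.
#' @export
memory_features <- function(gtrials) {
  rows <- data.frame(ecc = numeric(0), gain = numeric(0), disp = numeric(0))
  for (g in gtrials) {
    ct <- preprocess(g)
    if (!ct$usable) next
    sac <- detect_saccades(ct)
    cond <- g$trial$condition
    disp <- window_dispersion(ct, sac, cond$flash_onset + 0.1, cond$go_onset)
    resp <- sac[sac$onset > cond$go_onset &
                  sac$onset <= cond$go_onset + g$trial$timeout &
                  sac$amplitude >= PRIMARY_SACCADE_MIN_AMP, , drop = FALSE]
    gain <- NA_real_
    if (nrow(resp) > 0) {
      p1 <- resp[1, ]
      u <- sign(cond$location)
      land <- landing_pos(ct, p1)
      take <- takeoff_pos(ct, p1)
      gain <- ((land[1] - take[1]) * u) / cond$eccentricity
    }
    rows <- rbind(rows, data.frame(ecc = cond$eccentricity, gain = gain,
                                   disp = disp))
  }
  gain_at <- function(e) {
    v <- rows$gain[rows$ecc == e]
    mean_or_na(v[!is.na(v)])
  }
  g5 <- gain_at(5); g10 <- gain_at(10); g15 <- gain_at(15)
  c(mg_fixation_dispersion = mean_or_na(rows$disp[!is.na(rows$disp)]),
    mg_mean_gain = mean(c(g5, g10, g15)),
    mg_gain_5 = g5, mg_gain_10 = g10, mg_gain_15 = g15)
}

#' Predictive saccade task features (4 values)
#'
#' Steps 2--12 of each trial are scored (step 1 is unpredictable and
#' discarded). A step's latency is the onset of the first saccade moving in
#' the step's direction within [-0.25, +0.5] s around the step time, minus
#' the step time (negative = anticipatory). `mean_latency` averages over
#' steps and trials; `mean_variance` is the variance of step latencies
#' (s^2); gain per step is the saccade amplitude over the 20 degree step
#' size; fixation dispersion comes from the pre-trial fixation.
#'
#' @param gtrials List of `oc_gaze_trial` from the predictive task.
#' @return Named numeric vector of the task's 4 features.
#' @export
predictive_features <- function(gtrials) {
  lats <- gains <- disps <- numeric(0)
  for (g in gtrials) {
    ct <- preprocess(g)
    if (!ct$usable) next
    sac <- detect_saccades(ct)
    cond <- g$trial$condition
    onsets <- cond$step_onsets
    xs <- cond$first_sign * PREDICTIVE_AMP * rep_len(c(1, -1), 12)
    disps <- c(disps, window_dispersion(ct, sac, 0, onsets[1]))
    used <- rep(FALSE, nrow(sac))
    for (k in 2:12) {
      step_dir <- sign(xs[k] - xs[k - 1])
      cand <- which(!used &
                      sac$onset >= onsets[k] - 0.25 &
                      sac$onset < onsets[k] + 0.5 &
                      sign(sac$dx) == step_dir &
                      sac$amplitude >= PRIMARY_SACCADE_MIN_AMP)
      if (length(cand) == 0) next
      i <- cand[1]
      used[i] <- TRUE
      lats <- c(lats, sac$onset[i] - onsets[k])
      gains <- c(gains, sac$amplitude[i] / (2 * PREDICTIVE_AMP))
    }
  }
  c(ps_fixation_dispersion = mean_or_na(disps[!is.na(disps)]),
    ps_mean_variance = if (length(lats) >= 2) stats::var(lats) else
      if (length(lats) == 1) 0 else NA_real_,
    ps_mean_latency = mean_or_na(lats),
    ps_mean_gain = mean_or_na(gains))
}

#' Assemble the 31 eye-movement features for a session
#'
#' @param session An `oc_session` containing all four gaze tasks.
#' @return Named numeric vector of length 31 in canonical order.
#' @export
assemble_eye_features <- function(session) {
  missing <- setdiff(GAZE_TASKS, names(session$gaze))
  if (length(missing) > 0)
    stop("session is missing gaze task(s): ", paste(missing, collapse = ", "))
  out <- c(proanti_features(session$gaze$prosaccade),
           pursuit_features(session$gaze$pursuit),
           memory_features(session$gaze$memory_guided),
           predictive_features(session$gaze$predictive))
  stats::setNames(as.numeric(out), EYE_FEATURE_NAMES)
}
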