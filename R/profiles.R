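#' Construct a group oculomotor/cognitive phenotype profile
#'
#' A profile collects the generative parameters that define a group's
#' oculomotor and cognitive phenotype: saccade latency and gain moments,
#' anti-saccade error rate, pursuit gain/delay and catch-up saccade rate,
#' memory-guided gain and failure rate, predictive anticipation probability,
#' fixation noise, blink rate, working-memory span abilities and Stroop
#' parameters. These are documented modelling assumptions, not estimates of
#' any real cohort.
#'
#' @param group Group label: `"young"`, `"control"` or `"mci"`.
#' @param saccade_latency_mean,saccade_latency_sd Reactive saccade latency
#'   moments (s).
#' @param anti_error_rate Probability of an initial erroneous pro-saccade on
#'   an anti-saccade trial.
#' @param saccade_gain_mean,saccade_gain_sd Saccade amplitude gain moments
#'   (landing eccentricity / target eccentricity).
#' @param pursuit_gain Smooth-pursuit velocity gain in (0, 1.2].
#' @param pursuit_delay Pursuit temporal lag behind the target (s).
#' @param catchup_rate Catch-up saccade rate during pursuit (saccades/s).
#' @param memory_gain_mean,memory_gain_sd Memory-guided saccade gain moments.
#' @param memory_fail_rate Probability a memory-guided trial has no response
#'   saccade.
#' @param predictive_anticipation Probability a predictive step is anticipated
#'   (negative latency).
#' @param predictive_latency_mean Mean anticipatory lead time (s, positive
#'   number; applied as a negative latency).
#' @param predictive_latency_sd SD of predictive step latencies (s).
#' @param fixation_noise_sd Fixational gaze noise SD (degrees).
#' @param blink_rate Blink rate (blinks/minute); blinks appear as invalid
#'   0.1--0.2 s gaps.
#' @param span_ability Expected maximum forward span list length.
#' @param span_bwd_deficit Ability decrement for backward relative to forward
#'   span (items), both modalities.
#' @param span_bwd_digit_extra Additional ability decrement specific to the
#'   backward digit span task (items); the MCI-sensitive parameter.
#' @param span_lapse Lapse probability (error below ability level).
#' @param stroop_rt_base Mean congruent Stroop reaction time (s).
#' @param stroop_interference Stroop interference cost added to incongruent
#'   RTs (s).
#' @param stroop_rt_sd Stroop RT noise SD (s).
#' @param stroop_error_rate_congruent,stroop_error_rate_incongruent Error
#'   probabilities per congruency.
#' @return An object of class `"oc_profile"` (named list).
#' @export
group_profile <- function(group,
                          saccade_latency_mean, saccade_latency_sd,
                          anti_error_rate,
                          saccade_gain_mean, saccade_gain_sd,
                          pursuit_gain, pursuit_delay, catchup_rate,
                          memory_gain_mean, memory_gain_sd, memory_fail_rate,
                          predictive_anticipation,
                          predictive_latency_mean, predictive_latency_sd,
                          fixation_noise_sd, blink_rate,
                          span_ability, span_bwd_deficit, span_bwd_digit_extra,
                          span_lapse,
                          stroop_rt_base, stroop_interference, stroop_rt_sd,
                          stroop_error_rate_congruent,
                          stroop_error_rate_incongruent) {
  p <- as.list(environment())
  probs <- c("anti_error_rate", "memory_fail_rate", "predictive_anticipation",
             "span_lapse", "stroop_error_rate_congruent",
             "stroop_error_rate_incongruent")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (p$pursuit_gain <= 0 || p$pursuit_gain > 1.2)
    stop("pursuit_gain must be in (0, 1.2]")
  sds <- c("saccade_latency_sd", "saccade_gain_sd", "memory_gain_sd",
           "predictive_latency_sd", "stroop_rt_sd", "fixation_noise_sd")
  for (nm in sds) if (p[[nm]] < 0) stop(nm, " must be >= 0")
  structure(p, class = "oc_profile")
}

#' Default group phenotype profiles
#'
#' Configurable defaults for the three groups. The qualitative structure is:
#' young adults beat elderly adults by at least one between-subject SD on
#' latency, gain, delay and variance-type parameters; the MCI profile differs
#' from elderly controls by a small (about 0.2 SD) correlated shift across all
#' oculomotor parameters plus a larger (about 0.7 SD) deficit specific to backward
#' digit span ability -- small per feature, detectable multivariately.
#'
#' @return Named list with `oc_profile` entries `young`, `control`, `mci`.
#' @export
default_profiles <- function() {
  young <- group_profile(
    "young",
    saccade_latency_mean = 0.200, saccade_latency_sd = 0.030,
    anti_error_rate = 0.08,
    saccade_gain_mean = 0.95, saccade_gain_sd = 0.05,
    pursuit_gain = 0.95, pursuit_delay = 0.100, catchup_rate = 0.8,
    memory_gain_mean = 0.90, memory_gain_sd = 0.08, memory_fail_rate = 0.02,
    predictive_anticipation = 0.55,
    predictive_latency_mean = 0.150, predictive_latency_sd = 0.120,
    fixation_noise_sd = 0.12, blink_rate = 10,
    span_ability = 7.5, span_bwd_deficit = 1.0, span_bwd_digit_extra = 0,
    span_lapse = 0.02,
    stroop_rt_base = 0.60, stroop_interference = 0.08, stroop_rt_sd = 0.10,
    stroop_error_rate_congruent = 0.02, stroop_error_rate_incongruent = 0.06)
  control <- group_profile(
    "control",
    saccade_latency_mean = 0.265, saccade_latency_sd = 0.055,
    anti_error_rate = 0.22,
    saccade_gain_mean = 0.88, saccade_gain_sd = 0.09,
    pursuit_gain = 0.85, pursuit_delay = 0.150, catchup_rate = 1.5,
    memory_gain_mean = 0.82, memory_gain_sd = 0.13, memory_fail_rate = 0.08,
    predictive_anticipation = 0.35,
    predictive_latency_mean = 0.120, predictive_latency_sd = 0.190,
    fixation_noise_sd = 0.18, blink_rate = 12,
    span_ability = 5.8, span_bwd_deficit = 1.0, span_bwd_digit_extra = 0,
    span_lapse = 0.05,
    stroop_rt_base = 0.78, stroop_interference = 0.13, stroop_rt_sd = 0.16,
    stroop_error_rate_congruent = 0.03, stroop_error_rate_incongruent = 0.08)
  # MCI: elderly-control values shifted by ~0.2 between-subject SD on every
  # oculomotor parameter (the between-subject CV is ~10%, see
  # draw_individual_profile), plus a ~0.7 SD backward-span deficit.
  mci <- group_profile(
    "mci",
    saccade_latency_mean = 0.271, saccade_latency_sd = 0.058,
    anti_error_rate = 0.27,
    saccade_gain_mean = 0.862, saccade_gain_sd = 0.095,
    pursuit_gain = 0.833, pursuit_delay = 0.153, catchup_rate = 1.65,
    memory_gain_mean = 0.804, memory_gain_sd = 0.135, memory_fail_rate = 0.10,
    predictive_anticipation = 0.31,
    predictive_latency_mean = 0.110, predictive_latency_sd = 0.200,
    fixation_noise_sd = 0.188, blink_rate = 12,
    span_ability = 5.7, span_bwd_deficit = 1.0, span_bwd_digit_extra = 0.55,
    span_lapse = 0.06,
    stroop_rt_base = 0.80, stroop_interference = 0.14, stroop_rt_sd = 0.17,
    stroop_error_rate_congruent = 0.035,
    stroop_error_rate_incongruent = 0.09)
  list(young = young, control = control, mci = mci)
}

#' Degenerate noiseless "ideal participant" profile
#'
#' All noise, error and impairment parameters at their degenerate values:
#' gains 1, delay 0, zero noise, no blinks, no lapses. Extracted features for
#' such a participant hit their ideal values (accuracy 1, gain 1, delay 0,
#' variance about 0), which anchors the feature-extraction validation.
#'
#' @param latency Fixed saccade latency (s); drawn with zero SD.
#' @return An `oc_profile` with group `"control"`.
#' @export
ideal_profile <- function(latency = 0.25) {
  group_profile(
    "control",
    saccade_latency_mean = latency, saccade_latency_sd = 0,
    anti_error_rate = 0,
    saccade_gain_mean = 1, saccade_gain_sd = 0,
    pursuit_gain = 1, pursuit_delay = 0, catchup_rate = 0,
    memory_gain_mean = 1, memory_gain_sd = 0, memory_fail_rate = 0,
    predictive_anticipation = 1,
    predictive_latency_mean = 0.15, predictive_latency_sd = 0,
    fixation_noise_sd = 0, blink_rate = 0,
    span_ability = 99, span_bwd_deficit = 0, span_bwd_digit_extra = 0,
    span_lapse = 0,
    stroop_rt_base = 0.6, stroop_interference = 0, stroop_rt_sd = 0,
    stroop_error_rate_congruent = 0, stroop_error_rate_incongruent = 0)
}

# Parameters scaled multiplicatively by individual jitter; "high is worse"
# parameters share a latent severity factor so individual oculomotor deficits
# are correlated (which is what makes multivariate fusion informative).
PROFILE_JITTER_CV <- 0.10
PROFILE_LATENT_RHO <- 0.5

.jitter_params <- c(
  "saccade_latency_mean", "saccade_gain_mean", "pursuit_gain",
  "pursuit_delay", "catchup_rate", "memory_gain_mean",
  "predictive_anticipation", "fixation_noise_sd",
  "span_ability", "stroop_rt_base", "stroop_interference")
# Direction in which the latent severity factor pushes each parameter
# (+1 = larger is worse, -1 = smaller is worse).
.severity_sign <- c(
  saccade_latency_mean = 1, saccade_gain_mean = -1, pursuit_gain = -1,
  pursuit_delay = 1, catchup_rate = 1, memory_gain_mean = -1,
  predictive_anticipation = -1, fixation_noise_sd = 1,
  span_ability = -1, stroop_rt_base = 1, stroop_interference = 1)

#' Draw an individual participant profile from a group profile
#'
#' Individual parameters are the group means scaled by lognormal-like jitter
#' with a ~10% coefficient of variation; a shared latent severity factor
#' (correlation ~0.5 across parameters) makes individual deficits correlated
#' across tasks. Probabilities are clipped to [0, 1], `pursuit_gain` to
#' (0, 1.2].
#'
#' @param profile Group `oc_profile`.
#' @param cv Coefficient of variation of the between-subject jitter.
#' @return An individual `oc_profile`.
#' @export
draw_individual_profile <- function(profile, cv = PROFILE_JITTER_CV) {
  if (cv == 0) return(profile)
  z <- stats::rnorm(1)
  rho <- PROFILE_LATENT_RHO
  out <- profile
  for (nm in .jitter_params) {
    e <- rho * .severity_sign[[nm]] * z + sqrt(1 - rho^2) * stats::rnorm(1)
    out[[nm]] <- profile[[nm]] * (1 + cv * e)
  }
  out$predictive_anticipation <- min(max(out$predictive_anticipation, 0), 1)
  out$pursuit_gain <- min(max(out$pursuit_gain, 1e-3), 1.2)
  out$span_ability <- max(out$span_ability, 0)
  out$catchup_rate <- max(out$catchup_rate, 0)
  out$pursuit_delay <- max(out$pursuit_delay, 0)
  out$saccade_latency_mean <- max(out$saccade_latency_mean, 0.08)
  out
}
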