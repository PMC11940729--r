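test_that("an ideal noiseless participant hits the ideal feature values", {
  ef <- fix_ideal_features()
  expect_length(ef, 31)
  expect_named(ef, oculocog:::EYE_FEATURE_NAMES)
  expect_equal(ef[["pa_pro_accuracy"]], 1)
  expect_equal(ef[["pa_anti_accuracy"]], 1)
  gains <- ef[c("pa_pro_gain", "pa_anti_gain", "mg_gain_5", "mg_gain_10",
                "mg_gain_15", "ps_mean_gain")]
  expect_true(all(abs(gains - 1) < 0.02))
  # injected fixed latency 0.25 s recovered within one sample
  expect_lt(abs(ef[["pa_pro_latency"]] - 0.25), 1 / 60)
  expect_lt(abs(ef[["pa_anti_latency"]] - 0.25), 1 / 60)
  # pursuit: zero delay, essentially zero error variance, no catch-ups
  delays <- ef[c("sp_mean_delay", "sp_delay_v_025", "sp_delay_v_04",
                 "sp_delay_h_025", "sp_delay_h_04")]
  expect_true(all(delays == 0))
  vars <- ef[c("sp_mean_variance", "sp_variance_v_025", "sp_variance_v_04",
               "sp_variance_h_025", "sp_variance_h_04")]
  expect_true(all(vars < 1e-3))
  expect_equal(ef[["sp_saccade_compensation"]], 0)
  # predictive: pure anticipation at -0.15 s; step onsets land on the
  # 60 Hz grid, so recovered latencies carry sub-sample quantization
  expect_equal(ef[["ps_mean_latency"]], -0.15, tolerance = 1e-3)
  expect_lt(ef[["ps_mean_variance"]], 1e-4)
  # dispersions of a noiseless fixation are zero
  expect_lt(ef[["pa_fixation_dispersion"]], 0.05)
})

test_that("mean features equal the average of their condition features", {
  tab <- fix_small_table()
  expect_equal(tab$pa_mean_accuracy,
               (tab$pa_pro_accuracy + tab$pa_anti_accuracy) / 2)
  expect_equal(tab$pa_mean_latency,
               (tab$pa_pro_latency + tab$pa_anti_latency) / 2)
  expect_equal(tab$pa_mean_gain, (tab$pa_pro_gain + tab$pa_anti_gain) / 2)
  expect_equal(tab$mg_mean_gain,
               (tab$mg_gain_5 + tab$mg_gain_10 + tab$mg_gain_15) / 3)
})

test_that("pursuit delay estimator is exact on noiseless traces across delays", {
  psch <- build_pursuit_schedule(0)
  for (d in c(0, 0.1, 0.25, 0.4)) for (i in c(1, 2)) {
    pr <- ideal_profile()
    pr$pursuit_delay <- d
    pr$pursuit_gain <- 0.9
    g <- simulate_gaze_trial(psch$trials[[i]], pr, seed = 3)
    ct <- preprocess(g)
    est <- oculocog:::estimate_pursuit_delay(ct, detect_saccades(ct),
                                             g$trial)
    expect_lte(abs(est$delay - d), 1 / 60 + 1e-9)
  }
})

test_that("injected memory-guided gain is recovered within 0.02", {
  pr <- ideal_profile()
  pr$memory_gain_mean <- 0.9
  s <- simulate_session("g9", "control", pr, seed = 3)
  ef <- assemble_eye_features(s)
  expect_equal(ef[["mg_gain_10"]], 0.9, tolerance = 0.02)
  expect_equal(ef[["mg_mean_gain"]], 0.9, tolerance = 0.02)
})

test_that("anti trials whose first saccade goes to the cue are errors", {
  pr <- ideal_profile()
  pr$anti_error_rate <- 1
  sch <- build_prosaccade_schedule(0)
  anti <- Filter(function(tr) tr$condition$type == "anti", sch$trials)
  set.seed(5)
  gts <- lapply(anti[1:8], simulate_gaze_trial, profile = pr)
  f <- proanti_features(gts)
  expect_equal(f[["pa_anti_accuracy"]], 0)
})

test_that("catch-up saccades produce positive saccade compensation", {
  pr <- ideal_profile()
  pr$pursuit_gain <- 0.8
  pr$catchup_rate <- 1.5
  psch <- build_pursuit_schedule(0)
  g <- simulate_gaze_trial(psch$trials[[1]], pr, seed = 2)
  f <- pursuit_features(list(g))
  expect_gt(f[["sp_saccade_compensation"]], 0)
  # oracle: the generator's ledger of injected catch-up amplitudes
  cond <- g$trial$condition
  path <- 4 * cond$amplitude * cond$freq * (g$trial$duration - cond$sine_onset)
  expect_equal(f[["sp_saccade_compensation"]],
               sum(g$injected$catchup_amplitudes) / path,
               tolerance = 0.25)
})

test_that("saccades during the memory delay are not scored as responses", {
  # hand-built trace: a saccade to the flash during the delay, none after
  # the go signal -> no response, gain missing
  msch <- build_memory_guided_schedule(0)
  tr <- msch$trials[[1]]
  n <- floor(tr$duration * 60) + 1
  t <- (seq_len(n) - 1) / 60
  x <- numeric(n)
  mid <- tr$condition$flash_onset + 1.0
  x[t >= mid] <- tr$condition$location  # instant jump mid-delay
  g <- structure(list(trial = tr,
                      samples = data.frame(t = t, x = x, y = 0,
                                           valid = TRUE),
                      injected = list()), class = "oc_gaze_trial")
  f <- memory_features(list(g))
  expect_true(is.na(f[[paste0("mg_gain_", tr$condition$eccentricity)]]))
})

test_that("predictive anticipation yields negative mean latency", {
  pr <- ideal_profile()   # anticipation probability 1, lead 0.15 s
  pr$predictive_latency_sd <- 0.0
  sch <- build_predictive_schedule(0)
  set.seed(6)
  gts <- lapply(sch$trials[1:5], simulate_gaze_trial, profile = pr)
  f <- predictive_features(gts)
  expect_lt(f[["ps_mean_latency"]], 0)
  expect_lt(abs(f[["ps_mean_latency"]] + 0.15), 0.01)
  expect_lt(f[["ps_mean_variance"]], 1e-3)
})

test_that("feature assembly is deterministic and validates task presence", {
  s <- fix_ideal_session()
  expect_identical(assemble_eye_features(s), assemble_eye_features(s))
  s2 <- s
  s2$gaze$pursuit <- NULL
  expect_error(assemble_eye_features(s2), "pursuit")
})
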