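test_that("group profiles order young < elderly and control ~ mci on eye parameters", {
  pr <- default_profiles()
  expect_setequal(names(pr), c("young", "control", "mci"))
  expect_lt(pr$young$saccade_latency_mean, pr$mci$saccade_latency_mean)
  expect_gt(pr$young$saccade_gain_mean, pr$control$saccade_gain_mean)
  expect_lt(pr$young$pursuit_delay, pr$control$pursuit_delay)
  # control-mci pursuit gain gap under one within-group SD (10% CV)
  expect_lt(abs(pr$control$pursuit_gain - pr$mci$pursuit_gain),
            0.10 * pr$control$pursuit_gain)
  # the MCI-specific working-memory deficit targets backward digit span
  expect_gt(pr$mci$span_bwd_digit_extra, pr$control$span_bwd_digit_extra)
})

test_that("profile invariants are enforced", {
  pr <- default_profiles()$young
  pr$anti_error_rate <- 1.5
  expect_error(do.call(group_profile, pr), "anti_error_rate")
  pr <- default_profiles()$young
  pr$pursuit_gain <- 1.5
  expect_error(do.call(group_profile, pr), "pursuit_gain")
})

test_that("samples sit on the 60 Hz grid", {
  g <- fix_ideal_session()$gaze$prosaccade[[1]]
  expect_equal(diff(g$samples$t), rep(1 / 60, nrow(g$samples) - 1),
               tolerance = 1e-12)
})

test_that("degenerate noiseless pursuit reproduces the target exactly", {
  sch <- build_pursuit_schedule(1)
  tr <- sch$trials[[1]]
  g <- simulate_gaze_trial(tr, ideal_profile(), seed = 4)
  tp <- target_position(tr, g$samples$t)
  expect_equal(g$samples$x, unname(tp[, "x"]), tolerance = 1e-9)
  expect_equal(g$samples$y, unname(tp[, "y"]), tolerance = 1e-9)
})

test_that("a forced 0.25 s latency departs fixation 15 samples after target onset", {
  # grid-aligned trial: fixation exactly 1 s, so the saccade command lands
  # exactly on sample 15 after the target-onset sample
  ev <- data.frame(onset = c(0, 1), x = c(0, 9.7), y = 0,
                   kind = c("fixation", "step"))
  tr <- oc_trial("prosaccade", list(direction = "right", type = "pro"),
                 ev, duration = 2, timeout = 1)
  g <- simulate_gaze_trial(tr, ideal_profile(latency = 0.25), seed = 1)
  on_i <- which(g$samples$t >= 1)[1]
  first_moved <- which(abs(g$samples$x) > 1e-9)[1]
  expect_equal(first_moved - on_i, 15 + 1)  # movement begins after t0
})

test_that("identical seeds give identical traces; different seeds differ", {
  sch <- build_prosaccade_schedule(2)
  pr <- default_profiles()$control
  a <- simulate_gaze_trial(sch$trials[[1]], pr, seed = 9)
  b <- simulate_gaze_trial(sch$trials[[1]], pr, seed = 9)
  expect_identical(a$samples, b$samples)
  d <- simulate_gaze_trial(sch$trials[[1]], pr, seed = 10)
  expect_false(identical(a$samples, d$samples))
})

test_that("simulate_gaze_trial rejects non-gaze trials", {
  st <- build_stroop_schedule(0)$trials[[1]]
  expect_error(simulate_gaze_trial(st, ideal_profile()), "not a gaze task")
})

test_that("behavioral simulation respects the degenerate contracts", {
  pr <- ideal_profile()  # unbounded span ability, no lapses, no errors
  b <- simulate_behavior(pr, seed = 3)
  for (task in c("span_fwd_vis", "span_bwd_vis", "span_fwd_digit",
                 "span_bwd_digit"))
    expect_true(all(b[[task]]$correct))
  expect_true(all(b$stroop$correct))
  # zero interference and zero RT noise: congruent and incongruent RTs equal
  expect_equal(mean(b$stroop$rt[b$stroop$congruent]),
               mean(b$stroop$rt[!b$stroop$congruent]))
  pr$stroop_error_rate_incongruent <- 1
  b2 <- simulate_behavior(pr, seed = 3)
  expect_equal(mean(b2$stroop$correct[!b2$stroop$congruent]), 0)
})

test_that("cohort generation is sized, labeled and reproducible", {
  one <- generate_cohort(0, 0, 1, seed = 5)
  expect_length(one, 1)
  expect_equal(one[[1]]$group, "mci")
  coh <- fix_small_cohort()
  expect_length(coh, 22)
  grp <- table(vapply(coh, function(s) s$group, character(1)))
  expect_equal(as.vector(grp[c("young", "control", "mci")]), c(6L, 8L, 8L))
  again <- generate_cohort(0, 0, 1, seed = 5)
  expect_identical(serialize_session(one[[1]]), serialize_session(again[[1]]))
})

test_that("latency recovery: mean detected pro-saccade latency within one sample", {
  pr <- default_profiles()$control
  pr$blink_rate <- 0
  coh <- generate_cohort(0, 20, 0, seed = 33, profiles = list(control = pr))
  errs <- unlist(lapply(coh, function(s) {
    vapply(s$gaze$prosaccade, function(g) {
      if (isTRUE(g$injected$error_first) || is.null(g$injected$latency))
        return(NA_real_)
      ct <- preprocess(g)
      if (!ct$usable) return(NA_real_)
      sac <- detect_saccades(ct)
      tt <- g$trial$events$onset[g$trial$events$kind == "step"][1]
      prim <- sac[sac$onset > tt & sac$amplitude >= 2, , drop = FALSE]
      if (nrow(prim) == 0) return(NA_real_)
      prim$onset[1] - tt - g$injected$latency
    }, numeric(1))
  }))
  errs <- errs[!is.na(errs)]
  se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 1 / 60 + 2 * se)
})

test_that("group-difference fidelity: young beats elderly; MCI differs on backward digit span", {
  tab <- fix_medium_table()
  scr <- group_difference_screen(tab)
  # latency/delay/variance effects are large enough to reach significance
  # even at this reduced cohort size; gain is checked by sign below
  key <- c("pa_mean_latency", "sp_mean_delay", "sp_mean_variance",
           "ps_mean_latency")
  sub <- scr[scr$feature %in% key, ]
  expect_true(all(sub$pass_young_elderly))
  # sign structure: young faster (negative latency t), higher gain, lower
  # variance/delay (t is young minus elderly)
  expect_lt(scr$t_young_elderly[scr$feature == "pa_mean_latency"], 0)
  expect_gt(scr$t_young_elderly[scr$feature == "pa_mean_gain"], 0)
  expect_lt(scr$t_young_elderly[scr$feature == "sp_mean_variance"], 0)
  # the MCI working-memory deficit points the right way (control > mci)
  expect_gt(scr$t_control_mci[scr$feature == "span_bwd_digit"], 0)
})
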