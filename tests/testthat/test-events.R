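make_gtrial <- function(x, y = NULL, valid = NULL) {
  n <- length(x)
  if (is.null(y)) y <- numeric(n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(list(trial = NULL,
                 samples = data.frame(t = (seq_len(n) - 1) / 60,
                                      x = x, y = y, valid = valid),
                 injected = list()),
            class = "oc_gaze_trial")
}

test_that("preprocess interpolates short gaps linearly and flags them", {
  # linear signal so interpolation across a 2-sample gap is exact
  x <- seq(0, 2, length.out = 60)
  valid <- rep(TRUE, 60)
  valid[20:21] <- TRUE  # baseline: no gaps at all
  ct0 <- preprocess(make_gtrial(x, valid = valid))
  expect_false(any(ct0$interpolated))
  expect_false(any(ct0$excluded))
  expect_true(ct0$usable)
  valid[20:21] <- FALSE
  g <- make_gtrial(x, valid = valid)
  g$samples$x[20:21] <- NA
  ct <- preprocess(g)
  expect_true(all(ct$interpolated[20:21]))
  expect_false(any(ct$excluded))
  # linear in, linear out (smoothing preserves order-2 polynomials)
  expect_equal(ct$x, x, tolerance = 1e-9)
})

test_that("long gaps are excluded and mostly-invalid trials flagged unusable", {
  x <- rep(0, 120)
  valid <- rep(TRUE, 120)
  valid[30:45] <- FALSE  # 267 ms gap: excluded, not interpolated
  g <- make_gtrial(x, valid = valid)
  g$samples$x[!valid] <- NA
  ct <- preprocess(g)
  expect_true(all(ct$excluded[30:45]))
  expect_false(any(ct$interpolated[30:45]))
  expect_true(ct$usable)
  valid2 <- rep(c(TRUE, FALSE, FALSE), 40)
  g2 <- make_gtrial(x, valid = valid2)
  ct2 <- preprocess(g2)
  expect_false(ct2$usable)
  expect_error(preprocess(make_gtrial(numeric(5))), "10 samples")
})

test_that("interpolated and excluded masks are disjoint", {
  x <- rnorm(200, 0, 0.1)
  valid <- rep(TRUE, 200)
  valid[50:51] <- FALSE
  valid[100:115] <- FALSE
  g <- make_gtrial(x, valid = valid)
  g$samples$x[!valid] <- NA
  ct <- preprocess(g)
  expect_false(any(ct$interpolated & ct$excluded))
})

test_that("speed is exact on constant and linear-ramp traces", {
  ct <- preprocess(make_gtrial(rep(1.5, 60)))
  expect_equal(compute_velocity(ct), rep(0, 60))
  # x(t) = 10 t deg -> 10 deg/s everywhere
  tgrid <- (0:59) / 60
  ct <- preprocess(make_gtrial(10 * tgrid))
  v <- compute_velocity(ct)
  expect_equal(v[3:58], rep(10, 56), tolerance = 1e-9)
  # isotropy: pure y motion at 5 deg/s
  cty <- preprocess(make_gtrial(numeric(60), y = 5 * tgrid))
  expect_equal(compute_velocity(cty)[3:58], rep(5, 56), tolerance = 1e-9)
})

test_that("a simulated 9.7 degree saccade yields exactly one accurate event", {
  sch <- build_prosaccade_schedule(0)
  pro_i <- which(vapply(sch$trials, function(tr)
    tr$condition$type == "pro", logical(1)))
  for (i in pro_i[1:5]) {
    g <- simulate_gaze_trial(sch$trials[[i]], ideal_profile(), seed = i)
    sac <- detect_saccades(preprocess(g))
    expect_equal(nrow(sac), 1)
    expect_equal(sac$amplitude, 9.7, tolerance = 0.1)
    expect_gt(sac$peak_velocity, 30)
    expect_gt(sac$offset, sac$onset)
  }
})

test_that("fixation noise alone produces no events at default noise levels", {
  msch <- build_memory_guided_schedule(0)
  pr <- ideal_profile()
  pr$memory_fail_rate <- 1   # whole trial is fixation
  pr$fixation_noise_sd <- default_profiles()$control$fixation_noise_sd
  set.seed(42)
  n_events <- replicate(60, {
    g <- simulate_gaze_trial(msch$trials[[1]], pr)
    nrow(detect_saccades(preprocess(g)))
  })
  expect_lte(mean(n_events), 0.05)
})

test_that("two saccades 500 ms apart give two ordered events", {
  ev <- data.frame(onset = c(0, 1), x = c(0, -9.7), y = 0,
                   kind = c("fixation", "step"))
  tr <- oc_trial("prosaccade", list(direction = "left", type = "anti"),
                 ev, duration = 3, timeout = 1.5)
  pr <- ideal_profile(latency = 0.2)
  pr$anti_error_rate <- 1   # error toward cue, then correction
  g <- simulate_gaze_trial(tr, pr, seed = 2)
  sac <- detect_saccades(preprocess(g))
  expect_equal(nrow(sac), 2)
  expect_lt(sac$onset[1], sac$onset[2])
  expect_lt(sac$offset[1], sac$onset[2])
})

test_that("saccade detection recovers injected events with high sensitivity", {
  pr <- default_profiles()$control
  pr$blink_rate <- 0
  sch <- build_prosaccade_schedule(5)
  set.seed(7)
  found <- vapply(sch$trials[1:40], function(tr) {
    g <- simulate_gaze_trial(tr, pr)
    n_inj <- 1L + as.integer(isTRUE(g$injected$error_first))
    sac <- detect_saccades(preprocess(g))
    tt <- tr$events$onset[tr$events$kind == "step"][1]
    sum(sac$onset > tt & sac$amplitude >= 2) >= n_inj
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("fixation epochs carry centroid and RMS dispersion", {
  ct <- preprocess(make_gtrial(rep(0, 120)))
  fx <- detect_fixations(ct, detect_saccades(ct))
  expect_equal(nrow(fx), 1)
  expect_equal(fx$dispersion, 0)
  # alternating +/-1 degree: every sample at distance 1 from the centroid
  ct2 <- preprocess(make_gtrial(numeric(120), y = numeric(120)))
  ct2$x <- rep(c(1, -1), 60)  # bypass smoothing for the arithmetic check
  d <- oculocog:::window_dispersion(ct2, detect_saccades(ct), 0, 2)
  expect_equal(d, 1.0)
})

test_that("a trial split by one saccade yields two fixation epochs", {
  g <- simulate_gaze_trial(build_prosaccade_schedule(0)$trials[[1]],
                           ideal_profile(), seed = 3)
  ct <- preprocess(g)
  sac <- detect_saccades(ct)
  fx <- detect_fixations(ct, sac)
  expect_equal(nrow(fx), 2)
  expect_lte(fx$end[1], sac$onset[1] + 1e-9)
  expect_gte(fx$start[2], sac$offset[1] - 1e-9)
})

test_that("dispersion is invariant under translation and rotation", {
  set.seed(8)
  x <- rnorm(200, 0, 0.3)
  y <- rnorm(200, 0, 0.3)
  base <- make_gtrial(x, y = y)
  ct <- preprocess(base)
  sac <- detect_saccades(ct)
  d0 <- oculocog:::window_dispersion(ct, sac, 0, 10)
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 5
  yr <- sin(th) * x + cos(th) * y - 3
  ctr <- preprocess(make_gtrial(xr, y = yr))
  dr <- oculocog:::window_dispersion(ctr, sac, 0, 10)
  expect_equal(dr, d0, tolerance = 1e-9)
})

test_that("events never overlap each other or excluded regions", {
  pr <- default_profiles()$mci
  sch <- build_predictive_schedule(3)
  set.seed(12)
  for (i in 1:6) {
    g <- simulate_gaze_trial(sch$trials[[i]], pr)
    ct <- preprocess(g)
    sac <- detect_saccades(ct)
    if (nrow(sac) > 1)
      expect_true(all(sac$onset_i[-1] > sac$offset_i[-nrow(sac)]))
    if (nrow(sac) > 0)
      for (k in seq_len(nrow(sac)))
        expect_false(any(ct$excluded[sac$onset_i[k]:sac$offset_i[k]]))
  }
})
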