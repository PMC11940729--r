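# Trace cleaning and event detection: the primitives every eye-movement
# feature is built from. Detection is a classical velocity-threshold scheme,
# parameterized for 60 Hz monocular data.

#' Preprocess a raw gaze trial
#'
#' Short invalid gaps (at most 75 ms) are linearly interpolated and flagged;
#' longer gaps are flagged as excluded. Positions are then smoothed with a
#' Savitzky-Golay filter (window 5 samples, polynomial order 2). Trials with
#' fewer than 50% valid samples are flagged unusable and excluded from
#' feature averages downstream.
#'
#' @param gtrial An `oc_gaze_trial` (or any list with a `samples` data frame
#'   holding `t`, `x`, `y`, `valid`).
#' @param max_gap Longest gap to interpolate (s).
#' @param sg_window,sg_order Savitzky-Golay window length (samples, odd) and
#'   polynomial order.
#' @return An object of class `"oc_clean_trace"`: list with `t`, `x`, `y`,
#'   `interpolated`, `excluded` (logical masks) and `usable` flag.
#' @export
preprocess <- function(gtrial, max_gap = 0.075, sg_window = 5, sg_order = 2) {
  s <- gtrial$samples
  n <- nrow(s)
  if (n < 10) stop("need at least 10 samples")
  valid <- s$valid & is.finite(s$x) & is.finite(s$y)
  usable <- mean(valid) >= 0.5
  interpolated <- excluded <- rep(FALSE, n)
  x <- s$x
  y <- s$y
  if (any(!valid)) {
    r <- rle(!valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    max_gap_samples <- round(max_gap * OCULOCOG_HZ)
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      interior <- starts[j] > 1 && ends[j] < n
      if (length(idx) <= max_gap_samples && interior) {
        interpolated[idx] <- TRUE
      } else {
        excluded[idx] <- TRUE
      }
    }
    if (any(interpolated) && sum(valid) >= 2) {
      x[interpolated] <- stats::approx(s$t[valid], s$x[valid],
                                       xout = s$t[interpolated])$y
      y[interpolated] <- stats::approx(s$t[valid], s$y[valid],
                                       xout = s$t[interpolated])$y
    }
    # excluded samples get nearest-valid placeholder coordinates so the
    # smoother stays finite; they remain masked out of all analyses
    if (any(excluded) && sum(valid) >= 2) {
      x[excluded] <- stats::approx(s$t[valid], s$x[valid],
                                   xout = s$t[excluded], rule = 2)$y
      y[excluded] <- stats::approx(s$t[valid], s$y[valid],
                                   xout = s$t[excluded], rule = 2)$y
    }
  }
  if (usable && n >= sg_window) {
    x <- signal::sgolayfilt(x, p = sg_order, n = sg_window)
    y <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
  }
  structure(list(t = s$t, x = x, y = y,
                 interpolated = interpolated, excluded = excluded,
                 usable = usable, trial = gtrial$trial,
                 injected = gtrial$injected),
            class = "oc_clean_trace")
}

#' Two-dimensional gaze speed
#'
#' Central differences at interior samples, one-sided differences at the
#' endpoints. Samples adjacent to excluded regions get `NA` speed so blink
#' edges cannot masquerade as saccades.
#'
#' @param trace An `oc_clean_trace`.
#' @return Numeric vector of speeds (degrees/second).
#' @export
compute_velocity <- function(trace) {
  n <- length(trace$t)
  dt <- 1 / OCULOCOG_HZ
  vx <- vy <- numeric(n)
  if (n >= 3) {
    idx <- 2:(n - 1)
    vx[idx] <- (trace$x[idx + 1] - trace$x[idx - 1]) / (2 * dt)
    vy[idx] <- (trace$y[idx + 1] - trace$y[idx - 1]) / (2 * dt)
  }
  vx[1] <- (trace$x[2] - trace$x[1]) / dt
  vy[1] <- (trace$y[2] - trace$y[1]) / dt
  vx[n] <- (trace$x[n] - trace$x[n - 1]) / dt
  vy[n] <- (trace$y[n] - trace$y[n - 1]) / dt
  v <- sqrt(vx^2 + vy^2)
  if (any(trace$excluded)) {
    bad <- which(trace$excluded)
    halo <- unique(pmin(pmax(c(bad - 1L, bad, bad + 1L), 1L), n))
    v[halo] <- NA_real_
  }
  v
}

#' Detect saccades by velocity threshold
#'
#' Maximal runs of speed above `threshold` lasting at least `min_duration`
#' samples become candidate events; onsets and offsets are refined outward to
#' the nearest local speed minimum below threshold. Events overlapping
#' excluded (blink) regions are dropped. Amplitude is the Euclidean
#' onset-to-offset displacement.
#'
#' @param trace An `oc_clean_trace`.
#' @param threshold Speed threshold (degrees/second).
#' @param min_duration Minimum event length in samples.
#' @param min_amplitude Events smaller than this (degrees) are discarded as
#'   noise.
#' @return A `data.frame` of class `"oc_saccades"`: one row per event with
#'   `onset`, `offset` (s), `onset_i`, `offset_i` (sample indices),
#'   `amplitude` (deg), `peak_velocity` (deg/s), `dx`, `dy` (unit direction)
#'   and `land_x`, `land_y` (deg).
#' @export
detect_saccades <- function(trace, threshold = 30, min_duration = 2,
                            min_amplitude = 0.2) {
  v <- compute_velocity(trace)
  n <- length(v)
  above <- !is.na(v) & v > threshold
  out <- data.frame(onset = numeric(0), offset = numeric(0),
                    onset_i = integer(0), offset_i = integer(0),
                    amplitude = numeric(0), peak_velocity = numeric(0),
                    dx = numeric(0), dy = numeric(0),
                    land_x = numeric(0), land_y = numeric(0))
  if (!any(above)) return(structure(out, class = c("oc_saccades",
                                                   "data.frame")))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  last_off <- 0L
  for (j in which(r$values & r$lengths >= min_duration)) {
    i0 <- starts[j]
    i1 <- ends[j]
    # the onset is the first above-threshold sample: central differences
    # already anticipate the movement by one sample at 60 Hz, so walking
    # back to a local speed minimum would systematically antedate onsets.
    # The offset is refined outward to the nearest local minimum below
    # threshold so the landing position is read after the eye settles.
    while (i1 < n && !is.na(v[i1 + 1]) && v[i1 + 1] < v[i1] &&
           v[i1 + 1] < threshold) i1 <- i1 + 1L
    if (i0 <= last_off) i0 <- last_off + 1L  # never overlap previous event
    if (i1 <= i0) next
    if (any(trace$excluded[i0:i1])) next
    # displacement measured between short settling windows flanking the
    # event: single endpoint samples still carry smoothing transients
    ep <- list(onset_i = i0, offset_i = i1)
    take <- takeoff_pos(trace, ep)
    land <- landing_pos(trace, ep)
    amp <- sqrt(sum((land - take)^2))
    if (amp < min_amplitude) next
    d <- (land - take) / max(amp, 1e-12)
    out <- rbind(out, data.frame(
      onset = trace$t[i0], offset = trace$t[i1],
      onset_i = i0, offset_i = i1,
      amplitude = amp, peak_velocity = max(v[i0:i1], na.rm = TRUE),
      dx = d[1], dy = d[2],
      land_x = land[1], land_y = land[2]))
    last_off <- i1
  }
  structure(out, class = c("oc_saccades", "data.frame"))
}

#' Detect fixation epochs
#'
#' Fixations are the complement of saccades and excluded regions, kept when
#' at least `min_duration` seconds long. The centroid is the mean position
#' and the dispersion is the root-mean-square distance of samples from the
#' centroid (degrees) -- a translation- and rotation-invariant spread
#' measure.
#'
#' @param trace An `oc_clean_trace`.
#' @param saccades Events from [detect_saccades()].
#' @param min_duration Minimum epoch duration (s).
#' @return `data.frame` with `start`, `end`, `cx`, `cy`, `dispersion`.
#' @export
detect_fixations <- function(trace, saccades, min_duration = 0.1) {
  n <- length(trace$t)
  in_sac <- rep(FALSE, n)
  if (nrow(saccades) > 0)
    for (k in seq_len(nrow(saccades)))
      in_sac[saccades$onset_i[k]:saccades$offset_i[k]] <- TRUE
  free <- !in_sac & !trace$excluded
  out <- data.frame(start = numeric(0), end = numeric(0), cx = numeric(0),
                    cy = numeric(0), dispersion = numeric(0))
  if (!any(free)) return(out)
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    i0 <- starts[j]
    i1 <- ends[j]
    if (trace$t[i1] - trace$t[i0] < min_duration) next
    xs <- trace$x[i0:i1]
    ys <- trace$y[i0:i1]
    cx <- mean(xs)
    cy <- mean(ys)
    out <- rbind(out, data.frame(
      start = trace$t[i0], end = trace$t[i1], cx = cx, cy = cy,
      dispersion = sqrt(mean((xs - cx)^2 + (ys - cy)^2))))
  }
  out
}

# Landing position read over a short settling window after the saccade
# offset: more robust than the single offset sample, whose position can
# still carry smoothing transients.
landing_pos <- function(trace, sac_row, window = 3L) {
  idx <- sac_row$offset_i:min(sac_row$offset_i + window, length(trace$t))
  idx <- idx[!trace$excluded[idx]]
  if (length(idx) == 0) idx <- sac_row$offset_i
  c(mean(trace$x[idx]), mean(trace$y[idx]))
}

# Take-off position read just before onset, skipping the one or two samples
# where smoothing already leaks the upcoming movement.
takeoff_pos <- function(trace, sac_row, window = 3L) {
  hi <- max(sac_row$onset_i - 2L, 1L)
  idx <- max(hi - window, 1L):hi
  idx <- idx[!trace$excluded[idx]]
  if (length(idx) == 0) idx <- max(sac_row$onset_i - 1L, 1L)
  c(mean(trace$x[idx]), mean(trace$y[idx]))
}

# RMS dispersion of samples within a time window, excluding saccadic and
# excluded samples. Returns NA when fewer than `min_n` samples remain.
window_dispersion <- function(trace, saccades, t0, t1, min_n = 6) {
  sel <- trace$t >= t0 & trace$t <= t1 & !trace$excluded
  if (nrow(saccades) > 0)
    for (k in seq_len(nrow(saccades)))
      sel[saccades$onset_i[k]:saccades$offset_i[k]] <- FALSE
  if (sum(sel) < min_n) return(NA_real_)
  xs <- trace$x[sel]
  ys <- trace$y[sel]
  sqrt(mean((xs - mean(xs))^2 + (ys - mean(ys))^2))
}
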