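#' Detect reversals in a centroid track
#'
#' Classifies motion as forward or backward by projecting the raw
#' frame-to-frame velocity onto a persistent reference heading. The
#' reference heading follows the direction of the velocity smoothed over one
#' undulation period while the animal moves forward, and is frozen during
#' backward motion, so the undulatory component (perpendicular to the
#' heading) cancels out of the projection. A forward-to-backward sign change
#' that persists for at least `min_duration` seconds counts as one reversal;
#' its duration runs to the backward-to-forward transition. Only reversal
#' onsets within the scoring window (default the first 120 s) contribute to
#' `count_in_window`.
#'
#' @param track a [worm_track()].
#' @param window_s scoring window, seconds.
#' @param speed_threshold minimum projected speed (um/s) treated as directed
#'   motion; a track moving slower than this for more than half the samples
#'   yields a no-motion warning and zero reversals.
#' @param min_duration persistence (s) required to accept a transition.
#' @param undulation_period_s assumed undulation period for smoothing, s.
#' @return object of class `reversal_record`: `onsets`, `durations`
#'   (seconds), `count_in_window`, `window_s`.
#' @export
detect_reversals <- function(track, window_s = 120, speed_threshold = 10,
                             min_duration = 0.5, undulation_period_s = 2) {
  fr <- track$frame_rate
  if (max(track$t_s) < window_s) {
    stopf("track (%.1f s) shorter than the scoring window (%g s)",
          max(track$t_s), window_s, class = "wormpcd_input_error")
  }
  dt <- 1 / fr
  vx <- diff(track$x_um) / dt
  vy <- diff(track$y_um) / dt
  speed <- sqrt(vx^2 + vy^2)
  if (mean(speed > speed_threshold) < 0.5) {
    warning("track is mostly stationary; no reversals scored")
    return(structure(list(onsets = numeric(0), durations = numeric(0),
                          count_in_window = 0L, window_s = window_s),
                     class = "reversal_record"))
  }
  w <- max(1L, round(undulation_period_s * fr))
  sx <- moving_average(vx, w)
  sy <- moving_average(vy, w)
  smag <- sqrt(sx^2 + sy^2)

  n <- length(vx)
  n_min <- max(1L, round(min_duration * fr))
  typical_speed <- stats::median(speed)
  # initial reference heading: first smoothed sample with clear motion
  i0 <- which(smag > 0.5 * typical_speed)[1]
  if (is.na(i0)) i0 <- which.max(smag)
  hx <- sx[i0] / smag[i0]
  hy <- sy[i0] / smag[i0]

  persists <- function(i, sgn) {
    j <- i:min(n, i + n_min - 1L)
    mean(sgn * (vx[j] * hx + vy[j] * hy) > 0) >= 0.8
  }
  state <- "F"
  onsets <- numeric(0)
  ends <- numeric(0)
  for (i in seq_len(n)) {
    proj <- vx[i] * hx + vy[i] * hy
    if (state == "F") {
      if (proj < -speed_threshold && persists(i, -1)) {
        onsets <- c(onsets, track$t_s[i])
        state <- "B"
      } else if (smag[i] > 0.5 * typical_speed &&
                 (sx[i] * hx + sy[i] * hy) / smag[i] > 0.5) {
        # update the reference only while the smoothed velocity is reliable:
        # approaching a reversal the centered average nearly cancels and its
        # direction is dominated by undulation, so updates require clear
        # magnitude and less than 60 degrees of rotation from the current
        # reference (genuine turns are ~10 degrees per movement step)
        hx <- sx[i] / smag[i]
        hy <- sy[i] / smag[i]
      }
    } else if (proj > speed_threshold && persists(i, 1)) {
      ends <- c(ends, track$t_s[i])
      state <- "F"
    }
  }
  if (length(ends) < length(onsets)) {
    ends <- c(ends, max(track$t_s)) # reversal running into the end
  }
  durations <- ends - onsets
  keep <- durations > 0
  onsets <- onsets[keep]
  durations <- durations[keep]
  structure(list(onsets = onsets, durations = durations,
                 count_in_window = sum(onsets <= window_s),
                 window_s = window_s),
            class = "reversal_record")
}

#' @export
print.reversal_record <- function(x, ...) {
  cat(sprintf("<reversal_record> %d reversals in %g s (mean duration %.2f s)\n",
              x$count_in_window, x$window_s,
              if (length(x$durations)) mean(x$durations) else NA_real_))
  invisible(x)
}

#' Segment a track into movement steps of five undulation periods
#'
#' The lateral deviation of the centroid from its smoothed path oscillates
#' once per undulation; undulation periods are delimited by successive
#' upward zero crossings of that deviation, and every five periods form one
#' movement step. Edge regions distorted by the smoothing window are
#' excluded, and a trailing partial step is discarded.
#'
#' @param track a [worm_track()].
#' @param waves_per_step undulation periods per movement step.
#' @param undulation_period_s assumed undulation period for smoothing, s.
#' @return object of class `movement_steps`: data.frame with `start_idx`,
#'   `end_idx`, `start_s`, `end_s`, `dx_um`, `dy_um`, `n_periods`.
#' @export
segment_movement_steps <- function(track, waves_per_step = 5,
                                   undulation_period_s = 2) {
  fr <- track$frame_rate
  w <- max(2L, round(undulation_period_s * fr))
  px <- moving_average(track$x_um, w)
  py <- moving_average(track$y_um, w)
  txv <- moving_average(c(diff(px), NA), w)
  tyv <- moving_average(c(diff(py), NA), w)
  tmag <- sqrt(txv^2 + tyv^2)
  tmag[tmag == 0 | is.na(tmag)] <- NA
  # signed lateral deviation: cross product of unit tangent and offset
  dev <- (txv * (track$y_um - py) - tyv * (track$x_um - px)) / tmag
  # snap numerically-zero deviations so ties at exact zero crossings are
  # resolved identically under rigid transforms of the track
  dev[abs(dev) < 1e-9 * max(abs(dev), na.rm = TRUE)] <- 0
  n <- length(dev)
  interior <- seq.int(ceiling(w / 2) + 1L, n - ceiling(w / 2))
  cross_up <- interior[which(dev[interior - 1L] < 0 & dev[interior] >= 0)]
  if (length(cross_up) < 2 * waves_per_step + 1) {
    stopf("fewer than two complete movement steps detected (%d crossings)",
          length(cross_up), class = "wormpcd_input_error")
  }
  bounds <- cross_up[seq(1L, length(cross_up), by = waves_per_step)]
  n_steps <- length(bounds) - 1L
  if (n_steps < 1) {
    stopf("fewer than two complete movement steps detected",
          class = "wormpcd_input_error")
  }
  steps <- data.frame(
    start_idx = bounds[seq_len(n_steps)],
    end_idx = bounds[seq_len(n_steps) + 1L]
  )
  steps$start_s <- track$t_s[steps$start_idx]
  steps$end_s <- track$t_s[steps$end_idx]
  steps$dx_um <- track$x_um[steps$end_idx] - track$x_um[steps$start_idx]
  steps$dy_um <- track$y_um[steps$end_idx] - track$y_um[steps$start_idx]
  steps$n_periods <- waves_per_step
  structure(steps, class = c("movement_steps", "data.frame"))
}

#' Turning angles between successive movement steps
#'
#' The interior angle at each step junction: 180 degrees for straight
#' motion, less than 180 for dorsal turns and more than 180 for ventral
#' turns. The turn sign is oriented by `dorsal_side`: with dorsal on the
#' left, a counterclockwise rotation of the step vector is a dorsal turn.
#'
#' @param steps a [segment_movement_steps()] result (or any data.frame with
#'   `dx_um`, `dy_um`).
#' @param dorsal_side `"left"` or `"right"`.
#' @return numeric vector of angles in degrees, in `(0, 360)`.
#' @export
turning_angles <- function(steps, dorsal_side = c("left", "right")) {
  dorsal_side <- match.arg(dorsal_side)
  if (nrow(steps) < 2) {
    stopf("need at least two movement steps", class = "wormpcd_input_error")
  }
  u <- cbind(steps$dx_um, steps$dy_um)
  lens <- sqrt(rowSums(u^2))
  if (any(lens == 0)) {
    stopf("zero-length step displacement at step %d", which(lens == 0)[1],
          class = "wormpcd_input_error")
  }
  n <- nrow(u)
  a <- u[-n, , drop = FALSE]
  b <- u[-1, , drop = FALSE]
  signed_ccw <- atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
                      a[, 1] * b[, 1] + a[, 2] * b[, 2]) * 180 / pi
  dorsal_turn <- if (dorsal_side == "left") signed_ccw else -signed_ccw
  ((180 - dorsal_turn) %% 360)
}

#' Welch's unpaired two-tailed t test
#'
#' Group-comparison test used for behavioral metrics: Welch's statistic with
#' Satterthwaite degrees of freedom and a two-tailed p value.
#'
#' @param sample_a,sample_b numeric samples, each with `n >= 2`.
#' @return list with `t`, `df`, `p`, and per-sample `n`, `mean`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stopf("each sample needs at least 2 finite values",
          class = "wormpcd_input_error")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stopf("both samples have zero variance; Welch's t is undefined",
          class = "wormpcd_input_error")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       n = c(length(sample_a), length(sample_b)),
       mean = c(mean(sample_a), mean(sample_b)))
}

#' Per-track behavior metrics table
#'
#' Bundles the reversal and turning-angle metrics for one track.
#'
#' @param track a [worm_track()].
#' @inheritParams detect_reversals
#' @inheritParams segment_movement_steps
#' @return one-row data.frame with `n_reversals`, `mean_duration_s`,
#'   `mean_turning_angle_deg`, `n_steps`.
#' @export
behavior_metrics <- function(track, window_s = 120, waves_per_step = 5,
                             undulation_period_s = 2) {
  rev <- detect_reversals(track, window_s,
                          undulation_period_s = undulation_period_s)
  ang <- tryCatch({
    st <- segment_movement_steps(track, waves_per_step, undulation_period_s)
    turning_angles(st, track$dorsal_side)
  }, error = function(e) numeric(0))
  data.frame(
    n_reversals = rev$count_in_window,
    mean_duration_s = if (length(rev$durations)) mean(rev$durations) else NA_real_,
    mean_turning_angle_deg = if (length(ang)) mean(ang) else NA_real_,
    n_steps = if (length(ang)) length(ang) + 1L else 0L
  )
}
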