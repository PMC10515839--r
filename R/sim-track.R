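#' Worm centroid track
#'
#' Time-stamped 2-D centroid path with a known dorsal orientation flag.
#'
#' @param t_s timestamps, seconds, strictly increasing.
#' @param x_um,y_um centroid coordinates, micrometres.
#' @param frame_rate sampling rate, Hz.
#' @param dorsal_side `"left"` or `"right"`: which side of the direction of
#'   travel is the animal's dorsal side.
#' @return object of class `worm_track`.
#' @export
worm_track <- function(t_s, x_um, y_um, frame_rate, dorsal_side = "left") {
  if (any(diff(t_s) <= 0)) {
    stopf("track timestamps must be strictly increasing",
          class = "wormpcd_config_error")
  }
  if (any(!is.finite(x_um)) || any(!is.finite(y_um))) {
    stopf("track coordinates must be finite", class = "wormpcd_config_error")
  }
  structure(list(t_s = t_s, x_um = x_um, y_um = y_um,
                 frame_rate = frame_rate, dorsal_side = dorsal_side),
            class = "worm_track")
}

#' @export
print.worm_track <- function(x, ...) {
  cat(sprintf("<worm_track> %d samples over %.1f s at %g Hz (dorsal = %s)\n",
              length(x$t_s), max(x$t_s), x$frame_rate, x$dorsal_side))
  invisible(x)
}

#' Simulate a crawling worm track
#'
#' The centroid path is a smooth heading path plus a sinusoidal undulation
#' perpendicular to the heading. Every five undulation periods make one
#' movement step; at each step boundary the heading rotates by the dorsal
#' bias (plus optional heading noise), so the programmed interior angle
#' between successive steps is `180 - dorsal_bias` degrees. Programmed
#' reversals negate motion along the heading for their duration while the
#' undulation continues. Dorsal is taken as `dorsal_side` of the direction
#' of travel; with `dorsal_side = "left"` a dorsal turn is a counterclockwise
#' heading rotation.
#'
#' @param config a [sim_config()]; only `config$track` and the seed are used.
#' @return list with `track` (a [worm_track()]) and `truth`: per-step-boundary
#'   programmed turning angles (degrees, 180 = straight, < 180 dorsal),
#'   step boundary times, per-step headings, and the reversal
#'   [event_train()].
#' @export
simulate_worm_track <- function(config) {
  validate_sim_config(config)
  tr <- config$track
  fr <- tr$frame_rate
  n <- floor(tr$duration * fr) + 1
  t_s <- (seq_len(n) - 1) / fr
  step_dur <- 5 * tr$period
  n_steps <- ceiling(tr$duration / step_dur)

  set.seed(derive_seed(config$random_seed, "track"))
  dorsal_sign <- if (tr$dorsal_side == "left") 1 else -1
  turns <- rep(tr$dorsal_bias, n_steps)
  if (tr$heading_noise > 0) {
    turns <- turns + stats::rnorm(n_steps, 0, tr$heading_noise)
  }
  # heading angle per step: cumulative dorsal rotations (degrees -> rad)
  psi_steps <- cumsum(c(0, dorsal_sign * turns[-n_steps])) * pi / 180
  step_of <- pmin(floor(t_s / step_dur) + 1, n_steps)
  psi <- psi_steps[step_of]

  direction <- rep(1, n)
  if (!is.null(tr$reversals) && length(tr$reversals$onsets)) {
    for (i in seq_along(tr$reversals$onsets)) {
      on <- tr$reversals$onsets[i]
      off <- on + tr$reversals$durations[i]
      direction[t_s >= on & t_s < off] <- -1
    }
  }

  # forward displacement integrated along the (piecewise-constant) heading
  dt <- 1 / fr
  vx <- direction * tr$speed * cos(psi)
  vy <- direction * tr$speed * sin(psi)
  base_x <- cumsum(c(0, vx[-n])) * dt
  base_y <- cumsum(c(0, vy[-n])) * dt
  lat <- tr$amplitude * sin(2 * pi * t_s / tr$period)
  x <- base_x - lat * sin(psi)
  y <- base_y + lat * cos(psi)

  rev_train <- if (is.null(tr$reversals) || !length(tr$reversals$onsets)) {
    event_train(numeric(0), numeric(0), tr$duration)
  } else {
    event_train(tr$reversals$onsets,
                pmin(tr$reversals$durations,
                     tr$duration - tr$reversals$onsets),
                tr$duration)
  }
  truth <- list(
    true_turn_angles = 180 - turns[-n_steps],
    step_boundaries = step_dur * seq_len(n_steps - 1),
    step_headings = psi_steps * 180 / pi,
    true_events = rev_train
  )
  list(track = worm_track(t_s, x, y, fr, tr$dorsal_side), truth = truth)
}
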