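track_config <- function(seed, reversals = NULL, dorsal_bias = 0,
                         heading_noise = 0, duration = 130,
                         dorsal_side = "left", period = 2) {
  sim_config(random_seed = seed, track = list(
    speed = 120, period = period, amplitude = 40,
    dorsal_bias = dorsal_bias, heading_noise = heading_noise,
    frame_rate = 20, duration = duration, dorsal_side = dorsal_side,
    reversals = reversals
  ))
}

test_that("reversal detection recovers programmed reversals and ignores noise", {
  fwd <- simulate_worm_track(track_config(1))$track
  expect_equal(detect_reversals(fwd)$count_in_window, 0L)

  prog <- list(onsets = c(20, 50, 85), durations = c(2, 3, 4))
  tr <- simulate_worm_track(track_config(2, reversals = prog))$track
  rec <- detect_reversals(tr)
  expect_equal(rec$count_in_window, 3L)
  expect_equal(rec$onsets, prog$onsets, tolerance = 0.15)
  expect_true(all(abs(rec$durations - prog$durations) <= 1 / 20 + 1e-9))

  # jitter-only track below the speed threshold
  set.seed(3)
  n <- 121 * 20 + 1
  jit <- worm_track((0:(n - 1)) / 20, cumsum(rnorm(n, 0, 0.05)),
                    cumsum(rnorm(n, 0, 0.05)), 20)
  expect_warning(rec0 <- detect_reversals(jit), "stationary")
  expect_equal(rec0$count_in_window, 0L)

  short <- worm_track((0:100) / 20, (0:100), rep(0, 101), 20)
  expect_error(detect_reversals(short), class = "wormpcd_input_error")
})

test_that("reversal recovery and false-positive rates hold across many tracks", {
  hits <- 0L
  total <- 0L
  spurious <- 0L
  for (s in 1:100) {
    onsets <- (s * 7) %% 25 + c(15, 45, 80)
    durs <- 1 + ((s + 0:2) %% 3)
    prog <- list(onsets = onsets, durations = durs)
    out <- simulate_worm_track(track_config(100 + s, reversals = prog,
                                            heading_noise = 6))
    rec <- detect_reversals(out$track)
    total <- total + length(onsets)
    for (i in seq_along(onsets)) {
      if (any(abs(rec$onsets - onsets[i]) < 0.5)) hits <- hits + 1L
    }
    spurious <- spurious +
      sum(vapply(rec$onsets, function(o) all(abs(o - onsets) >= 0.5),
                 logical(1)))
  }
  expect_gte(hits / total, 0.95)
  expect_lte(spurious / total, 0.05)
})

test_that("movement-step segmentation counts five-wave steps", {
  # 22 undulation periods -> 20 interior periods -> exactly 4 steps
  cfg <- track_config(4, duration = 44)
  tr <- simulate_worm_track(cfg)$track
  steps <- segment_movement_steps(tr)
  expect_equal(nrow(steps), 4)
  expect_true(all(steps$n_periods == 5))
  expect_true(all(steps$end_idx > steps$start_idx))

  # straight noiseless track: step vectors parallel
  ang <- turning_angles(steps, "left")
  expect_true(all(abs(ang - 180) < 1))

  short <- worm_track((0:200) / 20, (0:200) * 6, rep(0, 201), 20)
  expect_error(segment_movement_steps(short), class = "wormpcd_input_error")
})

test_that("step boundaries land within one undulation period of ground truth", {
  # the segmenter cannot see the degenerate crossing at t = 0, so its
  # five-period grid may sit up to one period after the programmed one
  period <- 2
  for (s in 1:50) {
    out <- simulate_worm_track(track_config(200 + s, dorsal_bias = 5,
                                            heading_noise = 3,
                                            duration = 80))
    steps <- segment_movement_steps(out$track)
    truth_starts <- c(0, out$truth$step_boundaries)
    for (b in steps$start_s) {
      expect_lte(min(abs(truth_starts - b)), period + 0.15)
    }
  }
})

test_that("turning angles follow the dorsal-ventral sign convention", {
  # collinear steps
  st <- data.frame(dx_um = c(1, 2, 3), dy_um = c(0, 0, 0))
  expect_equal(turning_angles(st, "left"), c(180, 180))

  # rotation oracle: explicit 2-D rotations of a base vector
  rot <- function(v, deg) {
    th <- deg * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  base <- c(10, 3)
  dorsal10 <- rbind(base, rot(base, 10), rot(base, 20)) # CCW = leftward
  st_d <- data.frame(dx_um = dorsal10[, 1], dy_um = dorsal10[, 2])
  expect_equal(turning_angles(st_d, "left"), c(170, 170), tolerance = 1e-9)
  expect_equal(turning_angles(st_d, "right"), c(190, 190), tolerance = 1e-9)

  ventral10 <- rbind(base, rot(base, -10), rot(base, -20))
  st_v <- data.frame(dx_um = ventral10[, 1], dy_um = ventral10[, 2])
  expect_equal(turning_angles(st_v, "left"), c(190, 190), tolerance = 1e-9)

  expect_error(turning_angles(data.frame(dx_um = c(1, 0), dy_um = c(0, 0)),
                              "left"),
               class = "wormpcd_input_error")
  expect_error(turning_angles(st[1, ], "left"),
               class = "wormpcd_input_error")
})

test_that("behavior metrics are invariant under rigid motions and flip under reflection", {
  prog <- list(onsets = c(30, 70), durations = c(2, 3))
  out <- simulate_worm_track(track_config(7, reversals = prog,
                                          dorsal_bias = 10,
                                          heading_noise = 2))
  tr <- out$track
  th <- 0.83
  rx <- cos(th) * tr$x_um - sin(th) * tr$y_um + 1234
  ry <- sin(th) * tr$x_um + cos(th) * tr$y_um - 567
  tr_rot <- worm_track(tr$t_s, rx, ry, tr$frame_rate, tr$dorsal_side)

  rec <- detect_reversals(tr)
  rec_rot <- detect_reversals(tr_rot)
  expect_equal(rec$count_in_window, rec_rot$count_in_window)
  expect_equal(rec$onsets, rec_rot$onsets, tolerance = 1e-9)

  ang <- turning_angles(segment_movement_steps(tr), "left")
  ang_rot <- turning_angles(segment_movement_steps(tr_rot), "left")
  expect_equal(ang, ang_rot, tolerance = 1e-6)

  # reflection (y -> -y) swaps dorsal and ventral: with the dorsal flag
  # flipped the dorsal-turn magnitude is preserved, without it the sign of
  # the turn flips. (Reflection also mirrors the undulation phase, shifting
  # detected step boundaries by half a period, so means are compared.)
  tr_ref <- worm_track(tr$t_s, tr$x_um, -tr$y_um, tr$frame_rate, "right")
  steps_ref <- segment_movement_steps(tr_ref)
  ang_ref_flagged <- turning_angles(steps_ref, "right")
  expect_equal(mean(ang_ref_flagged), mean(ang), tolerance = 0.02)
  ang_ref_unflagged <- turning_angles(steps_ref, "left")
  expect_equal(mean(ang_ref_unflagged) - 180, -(mean(ang) - 180),
               tolerance = 0.4)
})

test_that("Welch's t test matches the independent formula oracle", {
  same <- welch_t_test(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  apart <- welch_t_test(1:5, 1:5 + 10)
  expect_lt(apart$p, 0.001)

  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welch_t_test(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }

  expect_error(welch_t_test(rep(1, 3), rep(2, 4)),
               class = "wormpcd_input_error")
  expect_error(welch_t_test(1, 1:5), class = "wormpcd_input_error")
})
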