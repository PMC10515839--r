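test_that("sorted-voxel extraction matches forced cases and the brute-force oracle", {
  mov <- make_test_movie(fill = 100)
  ann <- make_annotation(3, x = 7, y = 7, z = 4)
  tr <- extract_raw_trace(mov, ann, "green")
  expect_equal(tr$values, rep(100, 3))

  # exactly 40 voxels at 200 inside an 11 x 11 x 5 region, rest 0
  mov2 <- make_test_movie(fill = 0)
  arr <- mov2$green
  arr[1, 3:4, 3:7, 3:6] <- 200 # 2*5*4 = 40 voxels within the region
  mov2$green <- arr
  tr2 <- extract_raw_trace(mov2, make_annotation(3, 7, 7, 4), "green")
  expect_equal(tr2$values[1], 200)

  # oracle equivalence on 100 random regions (clipped and interior)
  set.seed(42)
  for (i in 1:100) {
    dims <- c(t = 1, z = sample(5:8, 1), y = sample(11:15, 1),
              x = sample(11:15, 1))
    mov3 <- make_test_movie(dims = dims)
    mov3$green <- array(runif(prod(dims), 0, 500), dims)
    cx <- sample(seq_len(dims[["x"]]), 1)
    cy <- sample(seq_len(dims[["y"]]), 1)
    cz <- sample(seq_len(dims[["z"]]), 1)
    tr3 <- extract_raw_trace(mov3, make_annotation(1, cx, cy, cz), "green")
    xs <- max(1, cx - 5):min(dims[["x"]], cx + 5)
    ys <- max(1, cy - 5):min(dims[["y"]], cy + 5)
    zs <- max(1, cz - 2):min(dims[["z"]], cz + 2)
    expect_identical(tr3$values[1],
                     oracle_top_mean(mov3$green[1, zs, ys, xs], 40))
  }
})

test_that("annotation gaps interpolate up to three volumes and go missing beyond", {
  mov <- make_test_movie(dims = c(t = 10, z = 7, y = 13, x = 13), fill = 1)
  ann <- make_annotation(10, 7, 7, 4)
  short_gap <- ann[-c(4, 5), ] # 2-volume gap: interpolated
  tr <- extract_raw_trace(mov, short_gap, "green")
  expect_false(any(is.na(tr$values)))

  long_gap <- ann[-(3:6), ] # 4-volume gap: left missing
  expect_message(tr2 <- extract_raw_trace(mov, long_gap, "green"), "missing")
  expect_equal(sum(is.na(tr2$values)), 4)
})

test_that("noise estimate is the per-volume 0.8 quantile aggregated by median", {
  mov <- make_test_movie(fill = 7)
  expect_equal(estimate_noise(mov, "green"), 7)

  # one volume holding the integers 0..100 exactly once: quantile is 80
  dims <- c(t = 1, z = 1, y = 1, x = 101)
  mov2 <- make_test_movie(dims = dims)
  mov2$green <- array(sample(0:100), dims)
  expect_equal(estimate_noise(mov2, "green"), 80)

  # jitter-free synthetic movie: noise floor below any neuron-region value
  cfg <- clean_movie_config(seed = 1, duration = 10,
                            noise_floor = c(red = 50, green = 50))
  sim <- simulate_calcium_movie(cfg, event_train(numeric(0), numeric(0), 10))
  est <- estimate_noise(sim$movie, "green")
  pos <- cfg$neuron_positions$RIML
  expect_lte(est, min(sim$movie$green[, pos[["z"]], pos[["y"]], pos[["x"]]]))
})

test_that("double-exponential fit recovers known curves", {
  times <- seq(0, 300, by = 0.25)

  fit_c <- fit_double_exponential(times, rep(5, length(times)))
  expect_lt(max(abs(fit_c$fitted_curve - 5) / 5), 1e-3)

  truth <- 3 * exp(-0.2 * times) + 2 * exp(-0.01 * times)
  fit2 <- fit_double_exponential(times, truth)
  expect_lt(abs(fit2$l1 - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit2$l2 - 0.01) / 0.01, 0.01)
  expect_lt(abs(fit2$a1 - 3) / 3, 0.01)
  expect_lt(abs(fit2$a2 - 2) / 2, 0.01)

  single <- 5 * exp(-0.1 * times)
  fit1 <- fit_double_exponential(times, single)
  expect_lt(max(abs(fit1$fitted_curve - single) / single), 1e-3)

  expect_error(fit_double_exponential(times[1:4], single[1:4]),
               class = "wormpcd_fit_error")
})

test_that("boxcar smoothing mode leaves rates intact on exact curves", {
  times <- seq(0, 600, by = 0.25)
  truth <- 4 * exp(-0.05 * times) + 6 * exp(-0.002 * times)
  fit <- fit_double_exponential(times, truth, smooth_s = 40)
  expect_lt(abs(fit$l1 - 0.05) / 0.05, 0.01)
  expect_lt(abs(fit$l2 - 0.002) / 0.002, 0.01)
  expect_lt(abs(fit$a1 - 4) / 4, 0.02)
  expect_lt(abs(fit$a2 - 6) / 6, 0.02)
})

test_that("artifact computation matches its definition and flags degeneracy", {
  times <- seq(0, 100, by = 0.25)
  curve <- 10 * exp(-0.01 * times)
  fit <- list(fitted_curve = curve)
  red <- curve + 3
  expect_equal(compute_artifact(red, fit, red_noise = 3),
               rep(1, length(times)))

  expect_error(compute_artifact(red, list(fitted_curve = rep(0, length(red))),
                                red_noise = 3),
               class = "wormpcd_fit_error")

  # known artifact recovered from a noise-free movie through the full path
  cfg <- clean_movie_config(seed = 1, duration = 480,
                            artifact = c(sd = 0.05, tau = 2),
                            bleach = list(
                              red = c(a1 = 0.35, l1 = 0.02, a2 = 0.65, l2 = 0.0015),
                              green = c(a1 = 0.3, l1 = 0.025, a2 = 0.7, l2 = 0.002)
                            ))
  ev <- event_train(numeric(0), numeric(0), 120)
  sim <- simulate_calcium_movie(cfg, ev)
  ann <- neuron_annotations(cfg)
  raw <- extract_raw_trace(sim$movie, ann[ann$neuron_id == "RIML", ], "red")
  tms <- (seq_along(raw$values) - 1) / cfg$frame_rate
  rfit <- fit_double_exponential(tms, raw$values, smooth_s = 40)
  art <- compute_artifact(raw, rfit, red_noise = 0)
  expect_gte(cor(art, sim$truth$true_artifact), 0.99)
})

test_that("trace correction normalizes, excludes events, and inverts the generator", {
  # no bleaching, unit artifact, no noise, no events: pure rescaling of a
  # flat-baseline trace (the bleach fit collapses to a constant)
  n <- 200
  fr <- 4
  vals <- rep(50, n)
  ev <- event_train(numeric(0), numeric(0), n / fr)
  ct <- correct_trace(vals, rep(1, n), 0, ev, fr)
  ratio <- ct$values / vals
  expect_lt(max(abs(ratio - ratio[1])) / ratio[1], 1e-6)
  expect_equal(median(ct$values), 1, tolerance = 1e-9)

  # full generative model at default SNR: corrected trace tracks 1 + dF/F
  cfg <- small_movie_config(seed = 6, duration = 300)
  ev2 <- simulate_event_train(cfg)
  sim <- simulate_calcium_movie(cfg, ev2)
  pr <- process_movie(sim$movie, neuron_annotations(cfg), ev2)
  for (nm in names(pr)) {
    expect_gte(cor(pr[[nm]]$corrected$values,
                   1 + sim$truth$true_calcium[, nm]), 0.95)
  }

  # degenerate case: every timepoint inside an event window
  ev_all <- event_train(0.5, n / fr - 1, n / fr)
  expect_error(correct_trace(vals, rep(1, n), 0, ev_all, fr, pre_s = 2,
                             post_s = 2),
               class = "wormpcd_fit_error")
})

test_that("green bleach rates are recovered when events cover under 30% of the recording", {
  errs <- c()
  for (s in 1:5) {
    cfg <- small_movie_config(seed = s, duration = 600)
    ev <- simulate_event_train(cfg)
    sim <- simulate_calcium_movie(cfg, ev)
    mask_frac <- mean(wormpcd:::event_mask(
      (seq_len(round(600 * 4)) - 1) / 4, ev))
    expect_lt(mask_frac, 0.30)
    pr <- process_movie(sim$movie, neuron_annotations(cfg), ev)
    gfit <- pr$RIML$corrected$bleach_fit
    errs <- c(errs, abs(gfit$l1 - 0.025) / 0.025,
              abs(gfit$l2 - 0.0020) / 0.0020)
  }
  # slow shared-artifact power is confounded with bleaching in any single
  # recording, so the guarantee is on the typical (median) error
  expect_lt(median(errs), 0.10)
  expect_lt(median(errs[c(FALSE, TRUE)]), 0.05) # slow rate: tighter
})

test_that("corrected traces do not depend on neuron processing order", {
  cfg <- small_movie_config(seed = 8, duration = 60)
  ev <- simulate_event_train(cfg)
  sim <- simulate_calcium_movie(cfg, ev)
  ann <- neuron_annotations(cfg)
  pr_ab <- process_movie(sim$movie, ann, ev)
  ann_rev <- ann[order(ann$neuron_id, decreasing = TRUE), ]
  pr_ba <- process_movie(sim$movie, ann_rev, ev)
  for (nm in names(pr_ab)) {
    expect_equal(pr_ab[[nm]]$corrected$values, pr_ba[[nm]]$corrected$values,
                 tolerance = 1e-10)
  }
})
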