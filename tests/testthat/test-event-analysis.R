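test_that("event alignment crops the right windows and drops boundary events", {
  fr <- 4
  vals <- seq(0, 99.75, by = 0.25) # values equal their own times
  ev <- event_train(50, 2, 100)
  aw <- align_to_events(vals, fr, ev, pre_s = 3, post_s = 3)
  expect_equal(nrow(aw$segments), 1)
  expect_length(aw$segments[1, ], 6 * fr + 1)
  expect_equal(aw$segments[1, ], seq(47, 53, by = 0.25))

  ev_edge <- event_train(c(1, 50), c(0.5, 2), 100)
  expect_message(aw2 <- align_to_events(vals, fr, ev_edge, 3, 3), "dropped")
  expect_equal(aw2$n_dropped, 1)
  expect_equal(nrow(aw2$segments), 1)

  # oracle equivalence on random traces and event placements
  set.seed(99)
  for (i in 1:100) {
    n <- sample(100:400, 1)
    v <- rnorm(n)
    onset <- runif(1, 0, n / fr - 0.6)
    evr <- event_train(onset, 0.5, n / fr)
    got <- suppressMessages(suppressWarnings(
      align_to_events(v, fr, evr, 3, 3)))
    want <- oracle_align(v, fr, onset, 3, 3)
    if (is.null(want)) {
      expect_equal(nrow(got$segments), 0)
    } else {
      expect_identical(got$segments[1, ], want)
    }
  }
})

test_that("event-triggered average applies the change-ratio formula", {
  fr <- 4
  ev <- event_train(c(20, 40, 60), rep(2, 3), 100)

  # constant trace: ratio identically zero with zero SEM
  aw <- align_to_events(rep(5, 400), fr, ev, 3, 3)
  eta <- event_triggered_average(aw)
  expect_true(all(eta$mean == 0))
  expect_true(all(eta$sem == 0))

  # forced ratio: baseline 10, post-onset 20 -> ratio 1
  v <- rep(10, 400)
  for (on in ev$onsets) v[(on * fr + 2):(on * fr + 13)] <- 20
  eta2 <- event_triggered_average(align_to_events(v, fr, ev, 3, 3))
  expect_equal(unname(eta2$mean[eta2$rel_time > 0]),
               rep(1, sum(eta2$rel_time > 0)))

  # degenerate baseline
  aw0 <- align_to_events(rep(0, 400), fr, ev, 3, 3)
  expect_error(event_triggered_average(aw0), class = "wormpcd_input_error")
})

test_that("event-triggered average recovers a known kernel from noisy traces", {
  fr <- 4
  n_ev <- 50
  onsets <- seq(15, by = 16, length.out = n_ev)
  dur <- max(onsets) + 12
  ev <- event_train(onsets, rep(2, n_ev), dur)
  cfg <- sim_config(random_seed = 21, frame_rate = fr, duration = dur)
  times <- (seq_len(round(dur * fr)) - 1) / fr
  dff <- wormpcd:::calcium_dff(times, ev, cfg$calcium_kernel)
  set.seed(13)
  trace <- (1 + dff) * (1 + rnorm(length(times), 0, 0.05))
  eta <- event_triggered_average(align_to_events(trace, fr, ev, 3, 3))

  peak_i <- which.max(eta$mean)
  expect_lte(abs(eta$rel_time[peak_i] - cfg$calcium_kernel[["rise"]]), 1 / fr)
  amp_err <- abs(eta$mean[peak_i] - cfg$calcium_kernel[["amplitude"]])
  expect_lte(amp_err, 2 * eta$sem[peak_i] + 1e-12)
})

test_that("change ratio is scale-free and shifts as the formula dictates", {
  fr <- 4
  ev <- event_train(c(30, 60), c(2, 2), 120)
  set.seed(5)
  v <- 10 + cumsum(rnorm(480, 0, 0.1))
  base <- event_triggered_average(align_to_events(v, fr, ev, 3, 3))
  scaled <- event_triggered_average(align_to_events(3.7 * v, fr, ev, 3, 3))
  expect_equal(scaled$mean, base$mean, tolerance = 1e-12)

  shifted <- event_triggered_average(align_to_events(v + 5, fr, ev, 3, 3))
  aw <- align_to_events(v, fr, ev, 3, 3)
  bsel <- aw$rel_time >= -3 & aw$rel_time <= 0
  f0 <- rowMeans(aw$segments[, bsel])
  direct <- colMeans(sweep(sweep(aw$segments + 5, 1, f0 + 5, "-"),
                           1, f0 + 5, "/"))
  expect_equal(shifted$mean, direct, tolerance = 1e-12)
})

test_that("spaghetti normalization divides each segment by its own baseline", {
  fr <- 4
  ev <- event_train(c(20, 50), c(2, 2), 100)
  aw <- normalize_spaghetti(rep(7, 400), fr, ev)
  expect_true(all(abs(aw$segments - 1) < 1e-12))
  expect_length(aw$rel_time, 10 * fr + 1)
  expect_equal(range(aw$rel_time), c(-3, 7))

  v <- rep(4, 400)
  for (on in ev$onsets) v[(on * fr + 2):(on * fr + 29)] <- 8
  aw2 <- normalize_spaghetti(v, fr, ev)
  expect_true(all(abs(aw2$segments[, aw2$rel_time > 0] - 2) < 1e-12))
})

test_that("pairwise correlations hit forced values and the analytic noise limit", {
  x <- sin(seq_len(200) / 7)
  pairs <- data.frame(class = "lr", a = "A", b = "B",
                      stringsAsFactors = FALSE)
  s_same <- pairwise_correlation(list(w1 = list(A = x, B = x)), pairs)
  expect_equal(s_same$per_pair$r, 1)
  s_neg <- pairwise_correlation(list(w1 = list(A = x, B = -x)), pairs)
  expect_equal(s_neg$per_pair$r, -1)

  # affine invariance and bounds
  s_aff <- pairwise_correlation(list(w1 = list(A = x, B = 2 * x + 3)), pairs)
  expect_equal(s_aff$per_pair$r, 1, tolerance = 1e-12)

  expect_warning(
    s0 <- pairwise_correlation(list(w1 = list(A = x, B = rep(1, 200))), pairs),
    "zero-variance")
  expect_equal(s0$n_excluded, 1L)

  # shared signal + independent noise: E[r] = shared / (shared + noise)
  set.seed(31)
  shared_var <- 1
  noise_var <- 0.5
  animals <- lapply(1:100, function(i) {
    s <- rnorm(300, 0, sqrt(shared_var))
    list(A = s + rnorm(300, 0, sqrt(noise_var)),
         B = s + rnorm(300, 0, sqrt(noise_var)))
  })
  names(animals) <- paste0("w", 1:100)
  sm <- pairwise_correlation(animals, pairs)
  expect_lt(abs(sm$class_means$mean_r - shared_var / (shared_var + noise_var)),
            0.05)
  expect_true(all(sm$per_pair$r >= -1 & sm$per_pair$r <= 1))
})

test_that("pair-class comparison runs Welch's test on per-animal means", {
  set.seed(8)
  pairs <- data.frame(class = c("lr", "wu"), a = c("A", "A"),
                      b = c("B", "C"), stringsAsFactors = FALSE)
  animals <- lapply(1:8, function(i) {
    s <- rnorm(200)
    list(A = s + rnorm(200, 0, 0.5), B = s + rnorm(200, 0, 0.5),
         C = s + rnorm(200, 0, 0.6))
  })
  names(animals) <- paste0("w", 1:8)
  sm <- pairwise_correlation(animals, pairs)
  res <- compare_pair_classes(sm, "lr", "wu")
  expect_true(is.finite(res$t) && is.finite(res$p))
  expect_gt(res$p, 0) # same shared signal: classes should not differ wildly
})
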