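#' Extract a raw sorted-voxel trace around an annotated neuron
#'
#' For every volume, the voxels in an `11 x 11 x 5` (x, y, z) region centred
#' on the annotated position are sorted in descending intensity and the mean
#' of the 40 brightest is taken. The region is clipped at the volume bounds;
#' if fewer than `top_k` voxels remain, all of them are averaged. Annotation
#' gaps of at most `max_gap` consecutive volumes are filled by linear
#' interpolation of the voxel coordinates; longer gaps yield `NA` values.
#'
#' @param movie a [two_channel_movie()].
#' @param annotation data.frame with columns `t_index` (1-based volume
#'   index), `neuron_id`, `x_vox`, `y_vox`, `z_vox` (1-based voxel
#'   coordinates); rows for one neuron.
#' @param channel `"red"` or `"green"`.
#' @param region region extent in voxels along `(x, y, z)`; odd integers.
#' @param top_k number of brightest voxels to average.
#' @param max_gap longest annotation gap (volumes) filled by interpolation.
#' @return object of class `raw_trace`: list with `neuron_id`, `channel`,
#'   `values` (one per volume, `NA` where unannotated), `frame_rate`,
#'   `region`, `top_k`, and `n_missing`.
#' @export
extract_raw_trace <- function(movie, annotation, channel = c("green", "red"),
                              region = c(11, 11, 5), top_k = 40,
                              max_gap = 3) {
  channel <- match.arg(channel)
  arr <- movie[[channel]]
  dims <- dim(arr) # (t, z, y, x)
  n_t <- dims[1]
  ids <- unique(annotation$neuron_id)
  if (length(ids) != 1) {
    stopf("annotation must describe exactly one neuron, got %d", length(ids),
          class = "wormpcd_format_error")
  }
  coords <- interpolate_annotation(annotation, n_t, max_gap)
  if (any(coords$x > dims[4] | coords$y > dims[3] | coords$z > dims[2] |
          coords$x < 1 | coords$y < 1 | coords$z < 1, na.rm = TRUE)) {
    stopf("annotated coordinates outside volume bounds for neuron '%s'", ids,
          class = "wormpcd_format_error")
  }
  hx <- (region[1] - 1) %/% 2
  hy <- (region[2] - 1) %/% 2
  hz <- (region[3] - 1) %/% 2
  values <- rep(NA_real_, n_t)
  for (t in seq_len(n_t)) {
    if (is.na(coords$x[t])) next
    xs <- max(1, coords$x[t] - hx):min(dims[4], coords$x[t] + hx)
    ys <- max(1, coords$y[t] - hy):min(dims[3], coords$y[t] + hy)
    zs <- max(1, coords$z[t] - hz):min(dims[2], coords$z[t] + hz)
    vox <- arr[t, zs, ys, xs]
    k <- min(top_k, length(vox))
    values[t] <- mean(sort(vox, decreasing = TRUE)[seq_len(k)])
  }
  n_missing <- sum(is.na(values))
  if (n_missing > 0) {
    message(sprintf("extract_raw_trace: %d/%d volumes missing for '%s' (%s)",
                    n_missing, n_t, ids, channel))
  }
  structure(list(neuron_id = ids, channel = channel, values = values,
                 frame_rate = movie$frame_rate, region = region,
                 top_k = top_k, n_missing = n_missing),
            class = "raw_trace")
}

# Per-volume voxel coordinates with short gaps linearly interpolated
# (rounded back to voxel indices). Gaps longer than max_gap stay NA.
interpolate_annotation <- function(annotation, n_t, max_gap) {
  x <- y <- z <- rep(NA_real_, n_t)
  idx <- annotation$t_index
  x[idx] <- annotation$x_vox
  y[idx] <- annotation$y_vox
  z[idx] <- annotation$z_vox
  fill <- function(v) {
    miss <- is.na(v)
    if (!any(miss) || all(miss)) return(v)
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      if (runs$lengths[r] > max_gap) next
      s <- starts[r]; e <- ends[r]
      if (s == 1 || e == n_t) next # no extrapolation at the edges
      v[s:e] <- round(stats::approx(c(s - 1, e + 1), c(v[s - 1], v[e + 1]),
                                    xout = s:e)$y)
    }
    v
  }
  list(x = fill(x), y = fill(y), z = fill(z))
}

#' Estimate the time-independent noise floor of a channel
#'
#' The 0.8 quantile (linear-interpolation convention) of all voxels is taken
#' per volume, then aggregated by the median across volumes. With sparse
#' fluorescent structures the bulk of voxels is background, so the 0.8
#' quantile sits at the background level while the median across volumes is
#' insensitive to bleaching trends.
#'
#' @param movie a [two_channel_movie()].
#' @param channel `"red"` or `"green"`.
#' @param prob quantile used per volume.
#' @return non-negative intensity scalar.
#' @export
estimate_noise <- function(movie, channel = c("green", "red"), prob = 0.8) {
  channel <- match.arg(channel)
  arr <- movie[[channel]]
  n_t <- dim(arr)[1]
  if (is.null(n_t) || n_t < 1) {
    stopf("movie has no volumes", class = "wormpcd_format_error")
  }
  per_vol <- vapply(seq_len(n_t), function(t) {
    stats::quantile(arr[t, , , ], prob, names = FALSE, type = 7)
  }, numeric(1))
  stats::median(per_vol)
}

#' Estimate the mean background intensity of a channel
#'
#' Median voxel intensity per volume, aggregated by the median across
#' volumes. With sparse fluorescent structures almost all voxels are
#' background, so this estimates the mean of the additive background
#' (including any zero-mean sensor jitter), whereas the 0.8-quantile noise
#' statistic of [estimate_noise()] sits about 0.84 background standard
#' deviations above that mean. The extraction pipeline subtracts this mean
#' before fitting bleach curves, where a constant offset error of even a
#' few intensity units visibly biases the slow decay rate.
#'
#' @inheritParams estimate_noise
#' @return intensity scalar.
#' @export
background_mean <- function(movie, channel = c("green", "red")) {
  channel <- match.arg(channel)
  arr <- movie[[channel]]
  n_t <- dim(arr)[1]
  if (is.null(n_t) || n_t < 1) {
    stopf("movie has no volumes", class = "wormpcd_format_error")
  }
  per_vol <- vapply(seq_len(n_t), function(t) {
    stats::median(arr[t, , , ])
  }, numeric(1))
  stats::median(per_vol)
}

#' Fit a double-exponential decay
#'
#' Least-squares fit of `a1 * exp(-l1 * t) + a2 * exp(-l2 * t)` with
#' non-negative rates and amplitudes, used for the photobleaching term of
#' each channel. Starting values come from log-linear fits: the final third
#' of the included points seeds the slow component, and the residual over
#' the first third seeds the fast one. Optimisation uses
#' Levenberg-Marquardt (`minpack.lm::nlsLM`) with bounds, falling back to
#' `optim(method = "L-BFGS-B")` on the sum of squares if the gradient is
#' degenerate (e.g. a constant series, for which the two components are not
#' separately identifiable but the fitted curve is still correct).
#'
#' A boxcar moving average scales each exponential component by the constant
#' `mean(exp(-l * j * dt))` over the window without changing its rate, so
#' `smooth_s > 0` suppresses faster disturbances (such as the shared motion
#' artifact) before fitting: the series is smoothed, the edge regions whose
#' windows are truncated are excluded, rates are taken from the smoothed
#' fit and amplitudes are rescaled by the known per-component factor. The
#' red-channel pipeline uses this; pure least squares is the default.
#'
#' @param times sample times, seconds (assumed evenly spaced when
#'   `smooth_s > 0`).
#' @param values series to fit, same length.
#' @param include optional logical mask of points to include (e.g. to
#'   exclude event windows); defaults to all finite points.
#' @param smooth_s boxcar width in seconds for artifact suppression
#'   (0 = none).
#' @return object of class `bleach_fit`: `a1`, `l1`, `a2`, `l2` (ordered so
#'   `l1 >= l2`), `fitted_curve` over all `times`, `residual_norm` over the
#'   included points, and `method`.
#' @export
fit_double_exponential <- function(times, values, include = NULL,
                                   smooth_s = 0) {
  if (is.null(include)) include <- rep(TRUE, length(values))
  include <- include & is.finite(values) & is.finite(times)
  if (smooth_s > 0) {
    dt <- stats::median(diff(times))
    n_all <- length(values)
    # cap the window so at least half the series survives the edge trim
    w <- max(1L, min(round(smooth_s / dt), n_all %/% 4))
    if (w < 3L) {
      return(fit_double_exponential(times, values, include, smooth_s = 0))
    }
    half <- ceiling(w / 2)
    n <- length(values)
    smoothed <- values
    smoothed[is.finite(values)] <- moving_average(values[is.finite(values)], w)
    interior <- seq_along(values) > half & seq_along(values) <= n - half
    fit <- fit_double_exponential(times, smoothed, include & interior,
                                  smooth_s = 0)
    # undo the per-component boxcar scaling on the amplitudes
    offs <- (seq_len(w) - (w + 1) / 2) * dt
    scale_of <- function(l) mean(exp(-l * offs))
    fit$a1 <- fit$a1 / scale_of(fit$l1)
    fit$a2 <- fit$a2 / scale_of(fit$l2)
    fit$fitted_curve <- fit$a1 * exp(-fit$l1 * times) +
      fit$a2 * exp(-fit$l2 * times)
    fit$method <- paste0(fit$method, "+boxcar")
    return(fit)
  }
  if (sum(include) < 5) {
    stopf("need at least 5 included points to fit a double exponential",
          class = "wormpcd_fit_error")
  }
  tt <- times[include]
  vv <- values[include]
  if (stats::median(vv) <= 0) {
    stopf("included values must be predominantly positive",
          class = "wormpcd_fit_error")
  }
  start <- init_double_exp(tt, vv)
  lower <- c(a1 = 0, l1 = 0, a2 = 0, l2 = 0)
  upper <- c(a1 = Inf, l1 = 10, a2 = Inf, l2 = 10)
  sse_of <- function(par) {
    sum((vv - par[["a1"]] * exp(-par[["l1"]] * tt) -
           par[["a2"]] * exp(-par[["l2"]] * tt))^2)
  }
  try_start <- function(st) {
    tryCatch({
      m <- minpack.lm::nlsLM(
        vv ~ a1 * exp(-l1 * tt) + a2 * exp(-l2 * tt),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      list(par = stats::coef(m), method = "nlsLM")
    }, error = function(e) NULL)
  }
  # multi-start over the fast rate guards against basin misses when the two
  # components are poorly separated
  fit <- NULL
  for (fac in c(1, 3, 1 / 3)) {
    st <- start
    st$l1 <- min(start$l1 * fac, upper[["l1"]])
    cand <- try_start(st)
    if (!is.null(cand) &&
        (is.null(fit) || sse_of(cand$par) < sse_of(fit$par))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    sse <- function(par) {
      sum((vv - par[1] * exp(-par[2] * tt) - par[3] * exp(-par[4] * tt))^2)
    }
    o <- stats::optim(unlist(start), sse, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
    if (o$convergence != 0 && o$value > sse(unlist(start))) {
      stopf("double-exponential fit did not converge (best SSE %.3g)",
            o$value, class = "wormpcd_fit_error")
    }
    fit <- list(par = stats::setNames(o$par, names(lower)),
                method = "L-BFGS-B")
  }
  p <- fit$par
  if (p[["l1"]] < p[["l2"]]) { # fast component first
    p <- c(a1 = p[["a2"]], l1 = p[["l2"]], a2 = p[["a1"]], l2 = p[["l1"]])
  }
  curve <- p[["a1"]] * exp(-p[["l1"]] * times) +
    p[["a2"]] * exp(-p[["l2"]] * times)
  structure(list(a1 = p[["a1"]], l1 = p[["l1"]],
                 a2 = p[["a2"]], l2 = p[["l2"]],
                 fitted_curve = curve,
                 residual_norm = sqrt(sum((vv - curve[include])^2)),
                 method = fit$method),
            class = "bleach_fit")
}

init_double_exp <- function(tt, vv) {
  n <- length(tt)
  third <- max(3L, n %/% 3L)
  tail_i <- (n - third + 1):n
  pos <- vv[tail_i] > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(vv[tail_i][pos]) ~ tt[tail_i][pos])
    a2 <- exp(stats::coef(lf)[[1]])
    l2 <- max(-stats::coef(lf)[[2]], 0)
  } else {
    a2 <- max(mean(vv[tail_i]), 1e-6)
    l2 <- 0
  }
  head_i <- 1:third
  resid <- vv[head_i] - a2 * exp(-l2 * tt[head_i])
  pos <- resid > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(resid[pos]) ~ tt[head_i][pos])
    a1 <- exp(stats::coef(lf)[[1]])
    l1 <- max(-stats::coef(lf)[[2]], 1e-4)
  } else {
    a1 <- max(vv[1] - a2, 0.05 * a2)
    l1 <- 5 / max(tt[n] - tt[1], 1)
  }
  list(a1 = a1, l1 = l1, a2 = a2, l2 = l2)
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf(
    "<bleach_fit> a1=%.4g l1=%.4g/s  a2=%.4g l2=%.4g/s  (resid %.3g, %s)\n",
    x$a1, x$l1, x$a2, x$l2, x$residual_norm, x$method))
  invisible(x)
}

#' Compute the shared multiplicative artifact series from the red channel
#'
#' The calcium-insensitive red channel is modeled as
#' `constant * bleach(t) * artifact(t) + noise`; dividing the noise-subtracted
#' red trace by its fitted double-exponential isolates the artifact, which
#' is then renormalized to mean 1.
#'
#' @param red_raw numeric red trace values (or a `raw_trace`).
#' @param red_fit a [fit_double_exponential()] result for the
#'   noise-subtracted red trace.
#' @param red_noise scalar noise floor from [estimate_noise()].
#' @param tol relative tolerance below which the fitted divisor is treated
#'   as degenerate.
#' @return numeric artifact series with mean 1 over non-missing samples.
#' @export
compute_artifact <- function(red_raw, red_fit, red_noise, tol = 1e-6) {
  values <- if (inherits(red_raw, "raw_trace")) red_raw$values else red_raw
  divisor <- red_fit$fitted_curve
  bad <- which(is.finite(divisor) & divisor <= tol * max(divisor, 0))
  if (max(divisor, na.rm = TRUE) <= 0 || length(bad)) {
    idx <- if (length(bad)) bad[1] else 1L
    stopf("degenerate bleach fit: divisor below tolerance at volume %d", idx,
          class = "wormpcd_fit_error")
  }
  artifact <- (values - red_noise) / divisor
  artifact / mean(artifact, na.rm = TRUE)
}

#' Artifact- and bleach-correct a green calcium trace
#'
#' Applies the three-term model to the green channel: subtracts the constant
#' noise floor, divides out the shared artifact, fits a double exponential
#' to the result using only timepoints outside event windows
#' (`[onset - pre_s, onset + duration + post_s]`, excluding the calcium rise
#' and decay tails), divides by that bleach curve, and rescales so the
#' median of the corrected trace outside events equals 1.
#'
#' @param green_raw numeric green trace values (or a `raw_trace`).
#' @param artifact mean-1 artifact series from [compute_artifact()].
#' @param green_noise scalar noise floor for the green channel.
#' @param events an [event_train()] on the recording timeline.
#' @param frame_rate volumes per second.
#' @param pre_s,post_s seconds excluded before each onset and after each
#'   event end when fitting the bleach curve.
#' @param detrend_s window (s) over which the artifact series is divided by
#'   its own moving average before use. The shared motion artifact is fast
#'   (seconds); slow drift in the artifact estimate is leakage from the red
#'   bleach fit and is indistinguishable from photobleaching, so it is left
#'   to the green bleach term rather than injected into the trace. 0
#'   disables.
#' @return object of class `corrected_trace`: `values` (normalized
#'   fluorescence, non-event median 1), `artifact_series`, `noise_estimate`,
#'   `bleach_fit`, `event_mask`, `frame_rate`, `neuron_id`.
#' @export
correct_trace <- function(green_raw, artifact, green_noise, events,
                          frame_rate, pre_s = 1, post_s = 3,
                          detrend_s = 40) {
  neuron_id <- if (inherits(green_raw, "raw_trace")) green_raw$neuron_id else NA
  values <- if (inherits(green_raw, "raw_trace")) green_raw$values else green_raw
  n_t <- length(values)
  times <- (seq_len(n_t) - 1) / frame_rate
  if (detrend_s > 0) {
    w <- min(round(detrend_s * frame_rate), n_t %/% 4)
    if (w >= 3) {
      artifact <- artifact / moving_average(artifact, w)
      artifact <- artifact / mean(artifact, na.rm = TRUE)
    }
  }
  g1 <- (values - green_noise) / artifact
  mask <- event_mask(times, events, pre_s, post_s)
  if (all(mask | !is.finite(g1))) {
    stopf("all timepoints fall inside event windows; no baseline to fit",
          class = "wormpcd_fit_error")
  }
  fit <- fit_double_exponential(times, g1, include = !mask)
  corrected <- g1 / fit$fitted_curve
  med <- stats::median(corrected[!mask], na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stopf("non-event median of corrected trace is not positive",
          class = "wormpcd_fit_error")
  }
  corrected <- corrected / med
  structure(list(neuron_id = neuron_id, values = corrected,
                 artifact_series = artifact, noise_estimate = green_noise,
                 bleach_fit = fit, event_mask = mask,
                 frame_rate = frame_rate),
            class = "corrected_trace")
}

event_mask <- function(times, events, pre_s = 1, post_s = 3) {
  mask <- rep(FALSE, length(times))
  if (is.null(events) || !length(events$onsets)) return(mask)
  for (i in seq_along(events$onsets)) {
    on <- events$onsets[i]
    off <- on + events$durations[i]
    mask <- mask | (times >= on - pre_s & times <= off + post_s)
  }
  mask
}

#' Run the full extraction pipeline on an annotated movie
#'
#' Convenience wrapper: per neuron, extracts raw red and green sorted-voxel
#' traces, estimates per-channel noise floors, fits the red bleach curve,
#' computes the shared artifact from the red channel and produces the
#' artifact- and bleach-corrected normalized green trace.
#'
#' @param movie a [two_channel_movie()].
#' @param annotations annotation data.frame covering one or more neurons.
#' @param events an [event_train()].
#' @param red_smooth_s boxcar width (s) for artifact suppression in the red
#'   bleach fit (see [fit_double_exponential()]).
#' @inheritParams extract_raw_trace
#' @return named list (one element per neuron) of lists with `raw_red`,
#'   `raw_green`, `red_fit`, `artifact`, `corrected`; plus attributes
#'   `noise_red` and `noise_green`.
#' @export
process_movie <- function(movie, annotations, events,
                          region = c(11, 11, 5), top_k = 40,
                          red_smooth_s = 40) {
  noise_red <- estimate_noise(movie, "red")
  noise_green <- estimate_noise(movie, "green")
  # bleach fits and corrections subtract the background MEAN; the 0.8
  # quantile overshoots it by ~0.84 sd, enough to bias the slow rate
  bg_red <- background_mean(movie, "red")
  bg_green <- background_mean(movie, "green")
  n_t <- dim(movie$red)[1]
  times <- (seq_len(n_t) - 1) / movie$frame_rate
  out <- lapply(split(annotations, annotations$neuron_id), function(ann) {
    raw_red <- extract_raw_trace(movie, ann, "red", region, top_k)
    raw_green <- extract_raw_trace(movie, ann, "green", region, top_k)
    red_fit <- fit_double_exponential(times, raw_red$values - bg_red,
                                      smooth_s = red_smooth_s)
    artifact <- compute_artifact(raw_red, red_fit, bg_red)
    corrected <- correct_trace(raw_green, artifact, bg_green, events,
                               movie$frame_rate)
    list(raw_red = raw_red, raw_green = raw_green, red_fit = red_fit,
         artifact = artifact, corrected = corrected)
  })
  attr(out, "noise_red") <- noise_red
  attr(out, "noise_green") <- noise_green
  attr(out, "background_red") <- bg_red
  attr(out, "background_green") <- bg_green
  out
}
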