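#' Two-channel volumetric movie
#'
#' Calcium-sensitive green and calcium-insensitive red channel stored as 4-d
#' intensity arrays indexed `(t, z, y, x)`.
#'
#' @param red,green numeric arrays of identical dimension `(t, z, y, x)`,
#'   non-negative.
#' @param frame_rate volumes per second.
#' @param voxel_size micrometres per voxel along `(x, y, z)`.
#' @return object of class `two_channel_movie`.
#' @export
two_channel_movie <- function(red, green, frame_rate, voxel_size) {
  if (!identical(dim(red), dim(green)) || length(dim(red)) != 4) {
    stopf("red and green must be 4-d arrays of identical shape",
          class = "wormpcd_format_error")
  }
  if (min(red) < 0 || min(green) < 0) {
    stopf("intensities must be non-negative", class = "wormpcd_format_error")
  }
  structure(list(red = red, green = green, frame_rate = frame_rate,
                 voxel_size = voxel_size),
            class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf("<two_channel_movie> %d volumes of %d x %d x %d (z,y,x) at %g Hz\n",
              d[1], d[2], d[3], d[4], x$frame_rate))
  invisible(x)
}

# Double-exponential bleach curve normalized so B(0) = a1 + a2.
bleach_curve <- function(times, b) {
  b[["a1"]] * exp(-b[["l1"]] * times) + b[["a2"]] * exp(-b[["l2"]] * times)
}

# Shared multiplicative artifact: AR(1) in log domain with stationary sd
# `sd` and correlation time `tau`, exponentiated and renormalized to mean 1.
simulate_artifact <- function(times, artifact, dt) {
  n <- length(times)
  sd_log <- artifact[["sd"]]
  if (sd_log == 0) {
    return(rep(1, n))
  }
  phi <- exp(-dt / artifact[["tau"]])
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_log)
  innov <- stats::rnorm(n - 1, 0, sd_log * sqrt(1 - phi^2))
  for (i in seq_len(n - 1)) {
    x[i + 1] <- phi * x[i] + innov[i]
  }
  a <- exp(x)
  a / mean(a)
}

# Anisotropic Gaussian PSF sampled on the voxel grid, flattened with z
# fastest, then y, then x (column-major order of an array dim (z, y, x)).
psf_field <- function(vc, pos, width) {
  zs <- seq_len(vc[["z"]])
  ys <- seq_len(vc[["y"]])
  xs <- seq_len(vc[["x"]])
  gz <- exp(-0.5 * ((zs - pos[["z"]]) / width[["z"]])^2)
  gy <- exp(-0.5 * ((ys - pos[["y"]]) / width[["y"]])^2)
  gx <- exp(-0.5 * ((xs - pos[["x"]]) / width[["x"]])^2)
  as.vector(outer(gz, as.vector(outer(gy, gx))))
}

#' Simulate a two-channel calcium movie with ground truth
#'
#' Generative counterpart of the extraction model. Each voxel of the green
#' channel follows `PSF(position) * F_cal(t) * B_g(t) * A(t)` plus a constant
#' noise floor and additive jitter, where `F_cal(t)` is the baseline
#' brightness scaled by `1 + dF/F(t)` from the event-locked calcium kernel;
#' the red channel uses a constant (calcium-insensitive) brightness with its
#' own double-exponential bleach curve `B_r(t)`; both channels share the
#' multiplicative artifact series `A(t)`.
#'
#' @param config a [sim_config()].
#' @param events an [event_train()]; defaults to [simulate_event_train()] on
#'   the same config.
#' @return list with elements `movie` (a [two_channel_movie()]) and `truth`,
#'   a list holding `true_calcium` (per-neuron dF/F matrix, neurons in
#'   columns), `true_bleach` (per-channel multiplicative series, unit at
#'   t = 0 up to amplitude normalization), `true_artifact` (mean-1 series),
#'   `true_events`, `times`, and the per-neuron PSF gain at the annotated
#'   voxel.
#' @export
simulate_calcium_movie <- function(config, events = NULL) {
  validate_sim_config(config)
  if (is.null(events)) {
    events <- simulate_event_train(config)
  }
  vc <- config$voxel_counts
  n_t <- round(config$duration * config$frame_rate)
  times <- (seq_len(n_t) - 1) / config$frame_rate
  dt <- 1 / config$frame_rate

  set.seed(derive_seed(config$random_seed, "movie"))
  art <- simulate_artifact(times, config$artifact, dt)
  b_red <- bleach_curve(times, config$bleach$red)
  b_green <- bleach_curve(times, config$bleach$green)

  neurons <- names(config$neuron_positions)
  dff <- vapply(neurons, function(nm) {
    calcium_dff(times, events, config$calcium_kernel)
  }, numeric(n_t))
  dff <- matrix(dff, nrow = n_t, dimnames = list(NULL, neurons))

  n_vox <- prod(vc)
  red_m <- matrix(0, n_t, n_vox)
  green_m <- matrix(0, n_t, n_vox)
  for (nm in neurons) {
    s <- psf_field(vc, config$neuron_positions[[nm]], config$psf_width)
    red_t <- config$baseline[["red"]] * b_red * art
    green_t <- config$baseline[["green"]] * (1 + dff[, nm]) * b_green * art
    red_m <- red_m + tcrossprod(red_t, s)
    green_m <- green_m + tcrossprod(green_t, s)
  }
  red_m <- red_m + config$noise_floor[["red"]]
  green_m <- green_m + config$noise_floor[["green"]]
  if (config$shot_noise_sd > 0) {
    set.seed(derive_seed(config$random_seed, "noise"))
    red_m <- red_m + stats::rnorm(length(red_m), 0, config$shot_noise_sd)
    green_m <- green_m + stats::rnorm(length(green_m), 0, config$shot_noise_sd)
  }
  red_m[red_m < 0] <- 0
  green_m[green_m < 0] <- 0

  dims <- c(n_t, vc[["z"]], vc[["y"]], vc[["x"]])
  movie <- two_channel_movie(array(red_m, dims), array(green_m, dims),
                             config$frame_rate, config$voxel_size)
  truth <- list(
    true_calcium = dff,
    true_bleach = list(red = b_red, green = b_green),
    true_artifact = art,
    true_events = events,
    times = times,
    psf_gain = vapply(neurons, function(nm) {
      s <- psf_field(vc, config$neuron_positions[[nm]], config$psf_width)
      max(s)
    }, numeric(1))
  )
  list(movie = movie, truth = truth)
}

#' Per-volume neuron annotations for a simulated movie
#'
#' Simulated neurons do not move, so the annotation table simply repeats each
#' configured voxel position for every volume. Coordinates are 1-based in
#' memory; the CSV writers convert to the 0-based on-disk convention.
#'
#' @param config a [sim_config()].
#' @param n_volumes number of volumes; defaults to the configured duration.
#' @return data.frame with columns `t_index`, `neuron_id`, `x_vox`, `y_vox`,
#'   `z_vox`.
#' @export
neuron_annotations <- function(config, n_volumes = NULL) {
  if (is.null(n_volumes)) {
    n_volumes <- round(config$duration * config$frame_rate)
  }
  do.call(rbind, lapply(names(config$neuron_positions), function(nm) {
    pos <- config$neuron_positions[[nm]]
    data.frame(
      t_index = seq_len(n_volumes), neuron_id = nm,
      x_vox = pos[["x"]], y_vox = pos[["y"]], z_vox = pos[["z"]],
      stringsAsFactors = FALSE
    )
  }))
}
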