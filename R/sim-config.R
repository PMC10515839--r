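#' Simulation configuration for synthetic recordings
#'
#' Bundles every tunable of the synthetic-data generators: imaging geometry,
#' per-channel double-exponential photobleaching, the shared multiplicative
#' artifact process, the event-locked calcium kernel, reversal-event
#' statistics and worm-track kinematics. Defaults describe a desk-scale
#' recording: 4 volumes/s with 0.4 um lateral / 1.2 um axial voxels
#' (matching the imaging regime the extraction model targets) on a reduced
#' 28 x 28 x 10 voxel grid, 600 s long, with two neurons.
#'
#' @param random_seed integer; master seed from which every generator derives
#'   a named substream.
#' @param frame_rate volumes per second.
#' @param duration recording length, seconds.
#' @param voxel_counts integer vector `(x, y, z)` of voxels per axis.
#' @param voxel_size micrometres per voxel along `(x, y, z)`.
#' @param neuron_positions named list of voxel coordinates `(x, y, z)`,
#'   1-based, one entry per neuron.
#' @param psf_width Gaussian PSF sigma in voxels along `(x, y, z)`.
#' @param bleach named list with elements `red` and `green`, each
#'   `c(a1, l1, a2, l2)`: amplitude fractions (summing to the unbleached
#'   level 1) and decay rates in 1/s of the double exponential.
#' @param artifact `c(sd, tau)`: stationary standard deviation of the
#'   log-domain AR(1) artifact and its correlation time in seconds.
#' @param noise_floor named `c(red=, green=)` constant background intensity.
#' @param shot_noise_sd standard deviation of additive intensity jitter.
#' @param baseline named `c(red=, green=)` peak neuron brightness above the
#'   noise floor at the PSF centre, in intensity units.
#' @param event_rate reversal events per minute.
#' @param event_duration `c(mean, sd)` of event durations, seconds.
#' @param refractory minimum gap between event onsets, seconds.
#' @param calcium_kernel `c(rise, decay, amplitude)`: linear rise time (s),
#'   exponential decay time constant (s) and peak dF/F of the event-locked
#'   calcium transient.
#' @param track named list of worm-track parameters: `speed` (um/s),
#'   `period` (undulation period, s), `amplitude` (undulation amplitude,
#'   um), `dorsal_bias` (degrees turned toward the dorsal side per movement
#'   step), `heading_noise` (sd of per-step heading noise, degrees),
#'   `frame_rate` (Hz), `duration` (s), `dorsal_side` ("left" or "right"),
#'   `reversals` (NULL or list with `onsets`, `durations` in seconds).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(random_seed = 1L,
                       frame_rate = 4,
                       duration = 600,
                       voxel_counts = c(x = 28, y = 28, z = 10),
                       voxel_size = c(x = 0.4, y = 0.4, z = 1.2),
                       neuron_positions = list(
                         RIML = c(x = 10, y = 14, z = 5),
                         RIMR = c(x = 19, y = 14, z = 5)
                       ),
                       psf_width = c(x = 1.5, y = 1.5, z = 1.0),
                       bleach = list(
                         red   = c(a1 = 0.35, l1 = 0.020, a2 = 0.65, l2 = 0.0015),
                         green = c(a1 = 0.30, l1 = 0.025, a2 = 0.70, l2 = 0.0020)
                       ),
                       artifact = c(sd = 0.05, tau = 2),
                       noise_floor = c(red = 100, green = 100),
                       shot_noise_sd = 2,
                       baseline = c(red = 600, green = 400),
                       event_rate = 3,
                       event_duration = c(mean = 2.5, sd = 1),
                       refractory = 5,
                       calcium_kernel = c(rise = 0.5, decay = 1.5, amplitude = 1.0),
                       track = list(
                         speed = 120, period = 2, amplitude = 40,
                         dorsal_bias = 0, heading_noise = 6,
                         frame_rate = 20, duration = 120,
                         dorsal_side = "left", reversals = NULL
                       )) {
  cfg <- list(
    random_seed = as.integer(random_seed), frame_rate = frame_rate,
    duration = duration, voxel_counts = voxel_counts,
    voxel_size = voxel_size, neuron_positions = neuron_positions,
    psf_width = psf_width, bleach = bleach, artifact = artifact,
    noise_floor = noise_floor, shot_noise_sd = shot_noise_sd,
    baseline = baseline, event_rate = event_rate,
    event_duration = event_duration, refractory = refractory,
    calcium_kernel = calcium_kernel, track = track
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_positive(cfg$frame_rate, "frame_rate")
  if (!is.numeric(cfg$duration) || length(cfg$duration) != 1 ||
      !is.finite(cfg$duration) || cfg$duration <= 0) {
    stopf("'duration' must be a single positive number",
          class = "wormpcd_config_error")
  }
  check_positive(cfg$voxel_counts, "voxel_counts")
  check_positive(cfg$voxel_size, "voxel_size")
  check_positive(cfg$psf_width, "psf_width")
  check_nonneg(cfg$event_rate, "event_rate")
  check_positive(cfg$event_duration[["mean"]], "event_duration mean")
  check_nonneg(cfg$event_duration[["sd"]], "event_duration sd")
  check_nonneg(cfg$refractory, "refractory")
  check_positive(cfg$calcium_kernel, "calcium_kernel")
  check_nonneg(cfg$artifact[["sd"]], "artifact sd")
  check_positive(cfg$artifact[["tau"]], "artifact tau")
  check_nonneg(cfg$noise_floor, "noise_floor")
  check_nonneg(cfg$shot_noise_sd, "shot_noise_sd")
  check_positive(cfg$baseline, "baseline")
  for (ch in c("red", "green")) {
    b <- cfg$bleach[[ch]]
    check_nonneg(b[c("l1", "l2")], paste(ch, "bleach rates"))
    check_positive(b[["a1"]] + b[["a2"]], paste(ch, "bleach amplitude"))
  }
  vc <- cfg$voxel_counts
  for (nm in names(cfg$neuron_positions)) {
    pos <- cfg$neuron_positions[[nm]]
    if (any(pos < 1) || any(pos > vc[c("x", "y", "z")])) {
      stopf("neuron '%s' lies outside the voxel volume", nm,
            class = "wormpcd_config_error")
    }
  }
  tr <- cfg$track
  check_positive(tr$speed, "track speed")
  check_positive(tr$period, "track period")
  check_nonneg(tr$amplitude, "track amplitude")
  check_positive(tr$frame_rate, "track frame_rate")
  check_positive(tr$duration, "track duration")
  if (!tr$dorsal_side %in% c("left", "right")) {
    stopf("track dorsal_side must be 'left' or 'right'",
          class = "wormpcd_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("  seed %d | %g Hz x %g s | grid %s voxels",
              x$random_seed, x$frame_rate, x$duration,
              paste(x$voxel_counts, collapse = "x")),
      sprintf("  neurons: %s", paste(names(x$neuron_positions), collapse = ", ")),
      sep = "\n")
  invisible(x)
}
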