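#' Reversal event train
#'
#' Container for reversal onsets and durations on a recording timeline.
#'
#' @param onsets onset times in seconds, strictly increasing.
#' @param durations event durations in seconds, strictly positive.
#' @param recording_length total recording length in seconds.
#' @return object of class `event_train`.
#' @export
event_train <- function(onsets, durations, recording_length) {
  onsets <- as.numeric(onsets)
  durations <- as.numeric(durations)
  if (length(onsets) != length(durations)) {
    stopf("onsets and durations must have equal length",
          class = "wormpcd_config_error")
  }
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    stopf("event onsets must be strictly increasing",
          class = "wormpcd_config_error")
  }
  if (any(durations <= 0)) {
    stopf("event durations must be strictly positive",
          class = "wormpcd_config_error")
  }
  if (any(onsets < 0) || any(onsets + durations > recording_length + 1e-9)) {
    stopf("events must lie within [0, recording_length]",
          class = "wormpcd_config_error")
  }
  structure(list(onsets = onsets, durations = durations,
                 recording_length = recording_length),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events over %g s\n",
              length(x$onsets), x$recording_length))
  invisible(x)
}

#' Simulate a reversal event train
#'
#' Draws reversal onsets as a Poisson process of rate `event_rate` thinned by
#' a hard refractory period: after each accepted onset the next candidate is
#' the refractory gap plus an exponential waiting time. Durations are drawn
#' from a normal distribution truncated to be positive, and clipped so no
#' event extends past the end of the recording.
#'
#' @param config a [sim_config()].
#' @return an [event_train()] plus a `seed_used` attribute.
#' @export
simulate_event_train <- function(config) {
  validate_sim_config(config)
  dur <- config$duration
  rate_s <- config$event_rate / 60
  if (rate_s == 0) {
    return(event_train(numeric(0), numeric(0), dur))
  }
  seed <- derive_seed(config$random_seed, "events")
  onsets <- numeric(0)
  set.seed(seed)
  t_cur <- stats::rexp(1, rate_s)
  while (t_cur < dur) {
    onsets <- c(onsets, t_cur)
    t_cur <- t_cur + config$refractory + stats::rexp(1, rate_s)
  }
  m <- config$event_duration[["mean"]]
  s <- config$event_duration[["sd"]]
  durations <- vapply(seq_along(onsets), function(i) {
    d <- stats::rnorm(1, m, s)
    while (d <= 0.1) d <- stats::rnorm(1, m, s)
    d
  }, numeric(1))
  if (length(onsets)) {
    durations <- pmin(durations, dur - onsets)
  }
  out <- event_train(onsets, durations, dur)
  attr(out, "seed_used") <- seed
  out
}

# Event-locked calcium transient: linear rise over `rise` seconds to
# `amplitude` dF/F, then exponential decay with time constant `decay`.
calcium_kernel_fun <- function(kernel) {
  rise <- kernel[["rise"]]
  decay <- kernel[["decay"]]
  amp <- kernel[["amplitude"]]
  function(dt) {
    out <- numeric(length(dt))
    up <- dt >= 0 & dt < rise
    dn <- dt >= rise
    out[up] <- amp * dt[up] / rise
    out[dn] <- amp * exp(-(dt[dn] - rise) / decay)
    out
  }
}

# dF/F time course on the sampling grid implied by (frame_rate, duration),
# summing kernels over all event onsets.
calcium_dff <- function(times, events, kernel) {
  k <- calcium_kernel_fun(kernel)
  dff <- numeric(length(times))
  for (on in events$onsets) {
    dff <- dff + k(times - on)
  }
  dff
}
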