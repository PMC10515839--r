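#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), the convention used
#' for all report columns. Base `round()` rounds half to even, which would
#' disagree with printed two-decimal tables at exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Centered moving average with edge values filled from the nearest fully
# averaged sample, so smoothed series keep the input length.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L || length(x) <= n) {
    return(x)
  }
  y <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  ok <- which(!is.na(y))
  y[seq_len(ok[1] - 1L)] <- y[ok[1]]
  last <- ok[length(ok)]
  if (last < length(y)) y[(last + 1L):length(y)] <- y[last]
  y
}

# Named substreams derived from one base seed so each generator draws from
# its own reproducible stream regardless of call order. Kept below 2^31.
STREAM_OFFSETS <- c(
  events = 11L, movie = 23L, track = 37L, mosaic = 53L,
  noise = 71L, pipeline = 89L
)

derive_seed <- function(seed, stream) {
  if (!stream %in% names(STREAM_OFFSETS)) {
    stop("unknown random substream: ", stream)
  }
  off <- STREAM_OFFSETS[[stream]]
  as.integer((abs(as.double(seed)) * 1009 + 97 * off) %% 2147483647)
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "wormpcd_error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stopf("'%s' must be strictly positive and finite", name,
          class = "wormpcd_config_error")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stopf("'%s' must be non-negative and finite", name,
          class = "wormpcd_config_error")
  }
  invisible(x)
}
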