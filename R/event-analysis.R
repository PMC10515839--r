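#' Align a trace to event onsets
#'
#' Crops one time-locked segment per event on a common relative time grid.
#' Onsets are snapped to the nearest sample; events whose window would
#' extend beyond the recording are dropped and counted.
#'
#' @param values numeric trace (or a `corrected_trace`).
#' @param frame_rate samples per second (taken from the trace object when
#'   one is supplied).
#' @param events an [event_train()].
#' @param pre_s,post_s window extent before and after each onset, seconds.
#' @return object of class `aligned_windows`: `segments` (events x time
#'   matrix), `rel_time` (seconds, 0 at onset), `n_dropped`, `frame_rate`.
#'   Zero retained events gives a 0-row matrix with a warning.
#' @export
align_to_events <- function(values, frame_rate = NULL, events,
                            pre_s = 3, post_s = 3) {
  if (inherits(values, "corrected_trace")) {
    frame_rate <- values$frame_rate
    values <- values$values
  }
  if (is.null(frame_rate)) {
    stopf("frame_rate required when 'values' is a bare vector",
          class = "wormpcd_config_error")
  }
  check_positive(c(pre_s, post_s), "pre_s/post_s")
  n_t <- length(values)
  pre_n <- round(pre_s * frame_rate)
  post_n <- round(post_s * frame_rate)
  rel_time <- (-pre_n:post_n) / frame_rate
  segs <- list()
  dropped <- 0L
  for (on in events$onsets) {
    idx0 <- round(on * frame_rate) + 1L
    lo <- idx0 - pre_n
    hi <- idx0 + post_n
    if (lo < 1L || hi > n_t) {
      dropped <- dropped + 1L
      next
    }
    segs[[length(segs) + 1L]] <- values[lo:hi]
  }
  if (!length(segs)) {
    warning("no events retained within the recording bounds")
    segments <- matrix(numeric(0), 0, length(rel_time))
  } else {
    segments <- do.call(rbind, segs)
  }
  if (dropped > 0) {
    message(sprintf("align_to_events: dropped %d out-of-bounds event(s)",
                    dropped))
  }
  structure(list(segments = segments, rel_time = rel_time,
                 n_dropped = dropped, frame_rate = frame_rate),
            class = "aligned_windows")
}

#' Event-triggered average change ratio
#'
#' For each aligned segment, the mean over the baseline interval (default
#' `[-3, 0]` s) gives `F0`; the change ratio is `(F(t) - F0) / F0`. The
#' ratios are averaged across events, with the standard error of the mean
#' per relative timepoint.
#'
#' @param windows an [align_to_events()] result.
#' @param baseline baseline interval in relative seconds `c(from, to)`.
#' @return object of class `event_triggered_average`: `mean`, `sem`,
#'   `rel_time`, `n_events`.
#' @export
event_triggered_average <- function(windows, baseline = c(-3, 0)) {
  seg <- windows$segments
  if (nrow(seg) < 1) {
    stopf("no aligned segments to average", class = "wormpcd_input_error")
  }
  bsel <- windows$rel_time >= baseline[1] & windows$rel_time <= baseline[2]
  if (!any(bsel)) {
    stopf("baseline interval lies outside the window",
          class = "wormpcd_config_error")
  }
  f0 <- rowMeans(seg[, bsel, drop = FALSE])
  if (any(f0 <= 0)) {
    stopf("non-positive baseline F0 for event %d", which(f0 <= 0)[1],
          class = "wormpcd_input_error")
  }
  ratios <- sweep(sweep(seg, 1, f0, "-"), 1, f0, "/")
  m <- colMeans(ratios)
  s <- if (nrow(seg) >= 2) {
    apply(ratios, 2, stats::sd) / sqrt(nrow(seg))
  } else {
    rep(0, ncol(seg))
  }
  structure(list(mean = m, sem = s, rel_time = windows$rel_time,
                 n_events = nrow(seg)),
            class = "event_triggered_average")
}

#' @export
print.event_triggered_average <- function(x, ...) {
  cat(sprintf("<event_triggered_average> %d events, window [%g, %g] s, peak %.3f at %+.2f s\n",
              x$n_events, min(x$rel_time), max(x$rel_time),
              max(x$mean), x$rel_time[which.max(x$mean)]))
  invisible(x)
}

#' Per-event baseline-normalized segments ("spaghetti" normalization)
#'
#' Crops a 10 s window from 3 s before to 7 s after each onset and divides
#' each segment by its own baseline `F0`, the mean of the first 3 s of the
#' window.
#'
#' @inheritParams align_to_events
#' @return an `aligned_windows` object whose segments are each divided by
#'   their own `F0`; carries a `baseline` attribute.
#' @export
normalize_spaghetti <- function(values, frame_rate = NULL, events,
                                pre_s = 3, post_s = 7) {
  aw <- align_to_events(values, frame_rate, events, pre_s, post_s)
  if (nrow(aw$segments) < 1) {
    return(aw)
  }
  bsel <- aw$rel_time <= 0
  f0 <- rowMeans(aw$segments[, bsel, drop = FALSE])
  if (any(f0 <= 0)) {
    stopf("non-positive baseline F0 for event %d", which(f0 <= 0)[1],
          class = "wormpcd_input_error")
  }
  aw$segments <- sweep(aw$segments, 1, f0, "/")
  attr(aw, "baseline") <- f0
  aw
}

#' Pairwise Pearson correlations between neuron traces, by pair class
#'
#' Computes, per animal, the Pearson correlation for each named neuron pair
#' (e.g. left-right pairs and normal-undead pairs) over the overlapping
#' non-missing samples of the full traces, then averages within each pair
#' class across animals.
#'
#' @param traces_by_animal named list (one element per animal) of named
#'   lists/matrices of numeric traces keyed by neuron id.
#' @param pair_classes data.frame with columns `class`, `a`, `b` naming the
#'   pair classes and member neuron ids.
#' @param min_overlap minimum number of overlapping samples.
#' @return object of class `correlation_summary`: `per_pair` (data.frame
#'   animal/class/a/b/r/n), `class_means` (data.frame class/mean_r/n_pairs/
#'   n_animals), `n_excluded`.
#' @export
pairwise_correlation <- function(traces_by_animal, pair_classes,
                                 min_overlap = 3) {
  rows <- list()
  n_excluded <- 0L
  for (animal in names(traces_by_animal)) {
    traces <- traces_by_animal[[animal]]
    for (i in seq_len(nrow(pair_classes))) {
      a <- pair_classes$a[i]
      b <- pair_classes$b[i]
      if (is.null(traces[[a]]) || is.null(traces[[b]])) next
      ok <- is.finite(traces[[a]]) & is.finite(traces[[b]])
      if (sum(ok) < min_overlap) {
        stopf("pair %s-%s in animal %s has fewer than %d overlapping samples",
              a, b, animal, min_overlap, class = "wormpcd_input_error")
      }
      va <- traces[[a]][ok]
      vb <- traces[[b]][ok]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning(sprintf(
          "zero-variance trace for pair %s-%s in animal %s; excluded",
          a, b, animal))
        n_excluded <- n_excluded + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal = animal, class = pair_classes$class[i], a = a, b = b,
        r = stats::cor(va, vb), n = sum(ok), stringsAsFactors = FALSE
      )
    }
  }
  per_pair <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(0), class = character(0),
               a = character(0), b = character(0),
               r = numeric(0), n = integer(0))
  class_means <- if (nrow(per_pair)) {
    agg <- stats::aggregate(r ~ class, per_pair, mean)
    agg$n_pairs <- stats::aggregate(r ~ class, per_pair, length)$r
    agg$n_animals <- vapply(agg$class, function(cl) {
      length(unique(per_pair$animal[per_pair$class == cl]))
    }, integer(1))
    names(agg)[names(agg) == "r"] <- "mean_r"
    agg
  } else {
    data.frame(class = character(0), mean_r = numeric(0),
               n_pairs = integer(0), n_animals = integer(0))
  }
  structure(list(per_pair = per_pair, class_means = class_means,
                 n_excluded = n_excluded),
            class = "correlation_summary")
}

#' Compare two correlation pair classes across animals
#'
#' Averages coefficients per animal within each class and applies Welch's
#' unpaired two-tailed t test to the per-animal means (the test used for
#' group comparisons throughout the package).
#'
#' @param summary a [pairwise_correlation()] result.
#' @param class_a,class_b pair-class labels to compare.
#' @return the [welch_t_test()] result.
#' @export
compare_pair_classes <- function(summary, class_a, class_b) {
  pp <- summary$per_pair
  per_animal <- function(cl) {
    sub <- pp[pp$class == cl, ]
    tapply(sub$r, sub$animal, mean)
  }
  welch_t_test(as.numeric(per_animal(class_a)),
               as.numeric(per_animal(class_b)))
}
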