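# On-disk conventions: CSV is UTF-8, comma-separated, "." decimal, header
# mandatory; voxel indices are 0-based on disk (1-based in memory); times in
# seconds, positions in micrometres, angles in degrees. Numeric columns are
# written with 17 significant digits so tables round-trip to better than
# 1e-12 relative.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

require_columns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s file '%s' is missing required column(s): %s", what, path,
          paste(missing, collapse = ", "), class = "wormpcd_schema_error")
  }
}

#' Write and read a two-channel movie as multi-page TIFF
#'
#' Each channel goes to one multi-page 32-bit-float TIFF with pages ordered
#' volume-major (all z planes of volume 1, then volume 2, ...). Intensities
#' are scaled into `[0, 1]` by a per-channel scale stored, together with the
#' geometry, in a JSON sidecar; a frames CSV maps each page to its
#' `(t_index, z_index)` (0-based).
#'
#' @param movie a [two_channel_movie()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named list of the four file paths, invisibly.
#' @export
write_movie <- function(movie, dir, prefix = "movie") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(movie$red) # (t, z, y, x)
  paths <- list(
    red = file.path(dir, paste0(prefix, "_red.tif")),
    green = file.path(dir, paste0(prefix, "_green.tif")),
    frames = file.path(dir, paste0(prefix, "_frames.csv")),
    meta = file.path(dir, paste0(prefix, "_meta.json"))
  )
  scales <- list()
  for (ch in c("red", "green")) {
    arr <- movie[[ch]]
    scale <- max(arr, 1e-12)
    pages <- vector("list", d[1] * d[2])
    k <- 1L
    for (t in seq_len(d[1])) {
      for (z in seq_len(d[2])) {
        pages[[k]] <- arr[t, z, , ] / scale
        k <- k + 1L
      }
    }
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 32L)
    scales[[ch]] <- scale
  }
  grid <- expand.grid(z_index = seq_len(d[2]) - 1L,
                      t_index = seq_len(d[1]) - 1L)
  frames <- data.frame(page = seq_len(nrow(grid)) - 1L,
                       t_index = grid$t_index, z_index = grid$z_index)
  utils::write.csv(frames, paths$frames, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(frame_rate = movie$frame_rate,
         voxel_size = as.list(movie$voxel_size),
         dim = list(t = d[1], z = d[2], y = d[3], x = d[4]),
         intensity_scale = scales),
    paths$meta, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' @rdname write_movie
#' @param path_red,path_green per-channel TIFF paths.
#' @param frames_path frames CSV path.
#' @param meta_path JSON sidecar path.
#' @export
read_movie <- function(path_red, path_green, frames_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- utils::read.csv(frames_path)
  require_columns(frames, c("page", "t_index", "z_index"), "frames",
                  frames_path)
  d <- c(meta$dim$t, meta$dim$z, meta$dim$y, meta$dim$x)
  assemble <- function(path, scale) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != d[1] * d[2]) {
      stopf("page count mismatch in '%s': expected %d (t) x %d (z) = %d, found %d",
            path, d[1], d[2], d[1] * d[2], length(pages),
            class = "wormpcd_format_error")
    }
    arr <- array(0, d)
    k <- 1L
    for (t in seq_len(d[1])) {
      for (z in seq_len(d[2])) {
        arr[t, z, , ] <- pages[[k]] * scale
        k <- k + 1L
      }
    }
    arr
  }
  red <- assemble(path_red, meta$intensity_scale$red)
  green <- assemble(path_green, meta$intensity_scale$green)
  two_channel_movie(red, green, meta$frame_rate,
                    unlist(meta$voxel_size))
}

#' Event-train CSV IO
#'
#' Events are stored as `onset_s,duration_s` rows.
#'
#' @param events an [event_train()].
#' @param path CSV path.
#' @return `write_events`: the path, invisibly. `read_events`: an
#'   [event_train()].
#' @export
write_events <- function(events, path) {
  write_table_csv(data.frame(onset_s = events$onsets,
                             duration_s = events$durations), path)
  invisible(path)
}

#' @rdname write_events
#' @param recording_length recording length in seconds; defaults to the end
#'   of the last event.
#' @export
read_events <- function(path, recording_length = NULL) {
  df <- utils::read.csv(path)
  require_columns(df, c("onset_s", "duration_s"), "events", path)
  if (any(df$duration_s <= 0)) {
    stopf("events file '%s' contains non-positive durations", path,
          class = "wormpcd_schema_error")
  }
  if (is.null(recording_length)) {
    recording_length <- if (nrow(df)) max(df$onset_s + df$duration_s) else 0
  }
  event_train(df$onset_s, df$duration_s, recording_length)
}

#' Worm-track CSV IO
#'
#' Tracks are stored as `t_s,x_um,y_um` rows; the dorsal-side flag and frame
#' rate live in the reader arguments (they are experiment metadata, not per
#' sample).
#'
#' @param track a [worm_track()].
#' @param path CSV path.
#' @return `write_track`: the path, invisibly. `read_track`: a
#'   [worm_track()].
#' @export
write_track <- function(track, path) {
  write_table_csv(data.frame(t_s = track$t_s, x_um = track$x_um,
                             y_um = track$y_um), path)
  invisible(path)
}

#' @rdname write_track
#' @param frame_rate sampling rate, Hz; inferred from timestamps if NULL.
#' @param dorsal_side `"left"` or `"right"`.
#' @export
read_track <- function(path, frame_rate = NULL, dorsal_side = "left") {
  df <- utils::read.csv(path)
  require_columns(df, c("t_s", "x_um", "y_um"), "track", path)
  if (is.null(frame_rate)) {
    frame_rate <- 1 / stats::median(diff(df$t_s))
  }
  worm_track(df$t_s, df$x_um, df$y_um, frame_rate, dorsal_side)
}

#' Neuron-annotation CSV IO
#'
#' Annotations are stored as `t_index,neuron_id,x_vox,y_vox,z_vox` with
#' 0-based indices on disk (converted to 1-based in memory).
#'
#' @param annotations in-memory annotation data.frame (1-based).
#' @param path CSV path.
#' @return `write_annotations`: the path, invisibly. `read_annotations`:
#'   the 1-based annotation data.frame.
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations
  for (nm in c("t_index", "x_vox", "y_vox", "z_vox")) df[[nm]] <- df[[nm]] - 1L
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("t_index", "neuron_id", "x_vox", "y_vox", "z_vox"),
                  "annotations", path)
  for (nm in c("t_index", "x_vox", "y_vox", "z_vox")) df[[nm]] <- df[[nm]] + 1L
  df
}

#' Trace-table CSV IO
#'
#' Long-format trace tables: `t_s,neuron_id,stage,value` with stage one of
#' `raw_red`, `raw_green`, `artifact`, `corrected`.
#'
#' @param traces data.frame in the long format above.
#' @param path CSV path.
#' @return `write_traces`: the path, invisibly. `read_traces`: the
#'   data.frame.
#' @export
write_traces <- function(traces, path) {
  require_columns(traces, c("t_s", "neuron_id", "stage", "value"),
                  "traces", path)
  write_table_csv(traces, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("t_s", "neuron_id", "stage", "value"), "traces", path)
  df
}

# Long-format trace table for one processed movie.
traces_long <- function(processed, frame_rate) {
  rows <- lapply(names(processed), function(nm) {
    pr <- processed[[nm]]
    n_t <- length(pr$corrected$values)
    t_s <- (seq_len(n_t) - 1) / frame_rate
    rbind(
      data.frame(t_s = t_s, neuron_id = nm, stage = "raw_red",
                 value = pr$raw_red$values),
      data.frame(t_s = t_s, neuron_id = nm, stage = "raw_green",
                 value = pr$raw_green$values),
      data.frame(t_s = t_s, neuron_id = nm, stage = "artifact",
                 value = pr$artifact),
      data.frame(t_s = t_s, neuron_id = nm, stage = "corrected",
                 value = pr$corrected$values)
    )
  })
  do.call(rbind, rows)
}

#' Run the simulate-extract-analyze pipeline end to end
#'
#' Simulates an annotated two-channel recording from `config`, writes the
#' inputs (movie TIFFs, events CSV, annotations CSV), runs the extraction
#' pipeline and the reversal-triggered average, writes the outputs (trace
#' CSV, event-triggered average CSV) and a run manifest recording the config
#' snapshot, seed, package version, input file digests, per-stage timings
#' and any warnings. Reruns with the same config reproduce identical trace
#' tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return list with `paths` (named file paths) and `manifest`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stopf("stage '%s' failed: %s", name, conditionMessage(e),
              class = "wormpcd_stage_error")
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  events <- stage("simulate_events", simulate_event_train(config))
  sim <- stage("simulate_movie", simulate_calcium_movie(config, events))
  ann <- neuron_annotations(config)
  paths <- stage("write_inputs", {
    p <- c(write_movie(sim$movie, out_dir, "movie"),
           list(events = file.path(out_dir, "events.csv"),
                annotations = file.path(out_dir, "annotations.csv")))
    write_events(events, p$events)
    write_annotations(ann, p$annotations)
    p
  })
  processed <- stage("extract", process_movie(sim$movie, ann, events))
  paths$traces <- stage("write_traces", {
    pt <- file.path(out_dir, "traces.csv")
    write_traces(traces_long(processed, config$frame_rate), pt)
    pt
  })
  eta_df <- stage("event_triggered_average", {
    if (length(events$onsets) >= 1) {
      do.call(rbind, lapply(names(processed), function(nm) {
        aw <- align_to_events(processed[[nm]]$corrected, events = events)
        if (nrow(aw$segments) < 1) return(NULL)
        eta <- event_triggered_average(aw)
        data.frame(rel_time_s = eta$rel_time, neuron_id = nm,
                   mean_change_ratio = eta$mean, sem = eta$sem,
                   n_events = eta$n_events)
      }))
    } else {
      NULL
    }
  })
  if (!is.null(eta_df)) {
    paths$eta <- file.path(out_dir, "eta.csv")
    write_table_csv(eta_df, paths$eta)
  }

  manifest <- list(
    tool = "wormpcd",
    version = as.character(utils::packageVersion("wormpcd")),
    seed = config$random_seed,
    config = unclass(config),
    input_digests = as.list(tools::md5sum(unlist(
      paths[c("red", "green", "events", "annotations")]))),
    timings_s = timings,
    warnings = warnings_seen
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}
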