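#!/usr/bin/env Rscript
# Generate the synthetic study inputs: one annotated two-channel recording
# (movie TIFFs + events + annotations) and a set of worm tracks, all with
# ground truth. Downstream scripts consume these files.

suppressMessages(library(wormpcd))

out_dir <- "scratch/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(random_seed = 1, duration = 600)
events <- simulate_event_train(cfg)
sim <- simulate_calcium_movie(cfg, events)
ann <- neuron_annotations(cfg)

paths <- write_movie(sim$movie, out_dir, "movie")
write_events(events, file.path(out_dir, "events.csv"))
write_annotations(ann, file.path(out_dir, "annotations.csv"))
jsonlite::write_json(
  list(config = unclass(cfg),
       true_bleach = sim$truth$true_bleach,
       true_artifact = sim$truth$true_artifact,
       true_calcium = as.data.frame(sim$truth$true_calcium)),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d-volume recording (%d neurons, %d reversal events)\n",
            dim(sim$movie$red)[1], length(cfg$neuron_positions),
            length(events$onsets)))

# tracks: an unbiased cohort and a dorsally biased cohort
track_cfg <- function(seed, bias) {
  sim_config(random_seed = seed, track = list(
    speed = 120, period = 2, amplitude = 40, dorsal_bias = bias,
    heading_noise = 6, frame_rate = 20, duration = 80,
    dorsal_side = "left", reversals = NULL))
}
dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
for (grp in c("unbiased", "dorsal10")) {
  bias <- if (grp == "dorsal10") 10 else 0
  for (s in 1:20) {
    tr <- simulate_worm_track(track_cfg(s + 100 * (grp == "dorsal10"), bias))
    write_track(tr$track,
                file.path(out_dir, "tracks", sprintf("%s_%02d.csv", grp, s)))
  }
}
cat("Wrote 40 tracks (20 unbiased, 20 with 10-degree dorsal bias)\n")
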