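#!/usr/bin/env Rscript

# Generate the exemplar synthetic recordings used by the downstream analysis
# drivers: a trigger-only monolayer, a driven re-entrant monolayer, and one
# rotor phantom of each core class. Movies are written as 16-bit multi-page
# TIFFs with ground truth alongside.

suppressPackageStartupMessages(library(rotormap))

out <- "results/recordings"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923L

message("-- trigger-only colony (1.4 mm^2, 4 triggers, 10 s) --")
lat <- generate_cell_lattice(1.4, mean_cell_diameter_um = 25, n_triggers = 4L,
                             seed = seed)
truth <- simulate_lattice(lat, duration_s = 10, seed = seed + 1L)
mov <- render_lattice_movie(truth, noise_sd = 0.05, seed = seed + 2L,
                            downsample = 3L)
write_movie(mov, file.path(out, "triggers.tif"))
write_label_mask(lat$raster, file.path(out, "triggers_labels.tif"))
trig_events <- data.frame(
  cell = rep(seq_along(truth$events), lengths(truth$events)),
  time_ms = unlist(truth$events))
write_results_table(trig_events, file.path(out, "triggers_events.csv"))
message(sprintf("  %d cells, %d events, movie %dx%d px",
                nrow(lat$centroids_um), nrow(trig_events),
                dim(mov$data)[1], dim(mov$data)[2]))

message("-- driven re-entrant colony (1.4 mm^2, line+patch core, 6 s) --")
lat_r <- generate_cell_lattice(1.4, mean_cell_diameter_um = 25,
                               n_triggers = 0L, seed = seed + 3L)
lat_r <- impose_block_structure(lat_r, "line_plus_patch", center_um = c(0, 0),
                                angle_deg = 160, length_um = 900,
                                patch_radius_um = 90, isolate_core = TRUE)
stim <- rotor_drive_stimuli(lat_r, period_ms = 400, t_start_ms = 50,
                            n_laps = 15L)
truth_r <- simulate_lattice(lat_r, duration_s = 6, seed = seed + 4L,
                            stimuli = stim)
mov_r <- render_lattice_movie(truth_r, noise_sd = 0.05, seed = seed + 5L,
                              downsample = 3L)
write_movie(mov_r, file.path(out, "reentry.tif"))
message(sprintf("  rotor period 400 ms, %d events", sum(lengths(truth_r$events))))

message("-- rotor phantoms, one per core class --")
for (type in c("line", "line_plus_patch", "multi_line")) {
  core <- core_structure(type, center = c(128, 128), angle_deg = 30,
                         length_px = if (type == "multi_line") 30 else 45,
                         patch_radius_px = 11)
  ph <- make_rotor_phantom(core, period_ms = 345, dim = c(256L, 256L),
                           duration_s = 3, noise_sd = 0.05, seed = seed + 6L)
  write_movie(ph$movie, file.path(out, paste0("phantom_", type, ".tif")))
  # true core as a run-length table (row, col_start, col_end), 0-based
  rle_rows <- do.call(rbind, lapply(seq_len(nrow(ph$truth$core_mask)), function(r) {
    v <- rle(ph$truth$core_mask[r, ])
    ends <- cumsum(v$lengths)
    starts <- ends - v$lengths + 1L
    keep <- v$values
    if (!any(keep)) return(NULL)
    data.frame(row = r - 1L, col_start = starts[keep] - 1L,
               col_end = ends[keep] - 1L)
  }))
  write_results_table(rle_rows,
                      file.path(out, paste0("phantom_", type, "_core.csv")))
  message(sprintf("  %s: %d true core pixels", type, sum(ph$truth$core_mask)))
}

message("done; recordings under ", out)
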