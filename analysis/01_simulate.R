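#!/usr/bin/env Rscript
# Stage 1 - simulate the study materials.
#
# Generates the reference full-channel VTS phantom (seeded, with complete
# ground truth) and the synthetic observer-score dataset used to calibrate
# the VEI, and writes their ground-truth tables under results/. Later
# stages regenerate the phantom deterministically from the same seed, so
# no voxel data needs to be carried between stages.

suppressPackageStartupMessages(library(vtsquant))
dir.create("results", showWarnings = FALSE)
seed <- 1L

spec <- reference_phantom_spec(seed = seed)
message("Growing the pseudovessel network ...")
truth <- generate_vessel_network(spec)
message(sprintf("  %d branches in %d trees, total centreline length %.0f um",
                length(truth$centerlines),
                length(unique(vapply(truth$centerlines, `[[`, 1L, "network"))),
                centerline_length(truth)))

message("Rasterizing channels (tubes, compartments, orbs, Col IV, noise) ...")
ph <- rasterize_phantom(spec, truth)
message(sprintf("  stack %s voxels, spacing %s um",
                paste(dim(ph$stack), collapse = "x"),
                paste(ph$stack$spacing, collapse = "/")))

# ground truth as plain tables
cl <- do.call(rbind, lapply(seq_along(ph$truth$centerlines), function(i) {
  b <- ph$truth$centerlines[[i]]
  data.frame(branch = i, network = b$network, depth = b$depth,
             z = b$points[, 1], y = b$points[, 2], x = b$points[, 3],
             radius_um = b$radius)
}))
write.csv(cl, "results/truth_centerlines.csv", row.names = FALSE)
cents <- do.call(rbind, lapply(names(ph$truth$cell_centroids), function(role) {
  cbind(data.frame(role = role), as.data.frame(ph$truth$cell_centroids[[role]]))
}))
write.csv(cents, "results/truth_cell_centroids.csv", row.names = FALSE)

# the calibration dataset: 200 groups, published model + small score noise
rank_tab <- generate_ranking_dataset(200, vei_model(), noise_sd = 0.02,
                                     seed = seed)
write.csv(rank_tab, "results/ranking_dataset.csv", row.names = FALSE)

message(sprintf(paste0("Wrote results/truth_centerlines.csv (%d points), ",
                       "truth_cell_centroids.csv (%d cells), ",
                       "ranking_dataset.csv (200 groups)."),
                nrow(cl), nrow(cents)))
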