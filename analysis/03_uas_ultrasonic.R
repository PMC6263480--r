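#!/usr/bin/env Rscript
# The two other sensing modalities on the same field. UAS: sample ~40% of
# the DSM's soil pixels, krige a DTM, subtract for the plant height map and
# take per-plot 1%-step pixel percentiles. Ultrasonic: convert voltages
# through the lab calibration (D = 29.116 V + 11.641, centimeter reading)
# and subtract from the measured sensor height.

suppressPackageStartupMessages(library(canopyscan))

dir.create("results", showWarnings = FALSE)
seed <- 42
scene <- generate_field_scene(
  scene_config(n_plots = 100, height_range = c(0.5, 0.8)), seed = seed)
ref <- generate_reference_heights(scene, campaign = 3, seed = seed)

# --- UAS chain ---
sim <- simulate_dsm(scene, gsd = 0.05, noise_sd = 0.02,
                    mosaic_error_sd = 0.04, surface_factor = 0.93 / 1.05,
                    seed = seed)
samples <- sample_soil_pixels(sim$dsm, sim$soil_mask, fraction = 0.4,
                              seed = seed)
message(sprintf("sampled %d of %d soil pixels (%.0f%%)",
                length(samples$z), sum(sim$soil_mask$values),
                100 * samples$sampling_fraction))
dtm <- interpolate_dtm(samples, sim$dsm, method = "kriging", stride = 4)
hmap <- height_map(sim$dsm, dtm)
message(sprintf("height map: %d negative cells out of %d",
                attr(hmap, "negative_cells"), length(hmap$values)))
lad <- uas_plot_ladders(hmap, plot_polygons_from_scene(scene), step = 1)
write_ladders_csv(lad, "results/uas_pixel_ladders.csv")
opt <- optimal_percentile(lad, ref)
message(sprintf("UAS optimal pixel percentile: %d%% (RMSE %.4f m, bias %+.4f m)",
                opt$percentile, opt$rmse, opt$bias))

# --- ultrasonic chain ---
us <- simulate_ultrasonic(scene, scan_pose(sensor_height = 2),
                          echo_depth_percentile = 40, noise_sd = 0.05,
                          seed = seed)
heights <- ultrasonic_heights_table(us, unit_scale = 0.01)
utils::write.csv(heights, "results/ultrasonic_heights.csv", row.names = FALSE)
message(sprintf(
  "ultrasonic: RMSE %.4f m, bias %+.4f m, %d negative reading(s)",
  rmse(heights$height_m, ref$height_m),
  bias(heights$height_m, ref$height_m), sum(heights$negative)))
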