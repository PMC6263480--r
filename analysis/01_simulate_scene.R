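#!/usr/bin/env Rscript
# Simulate one synthetic wheat field and write every sensor artifact for a
# single mid-season campaign: a static LiDAR scan (PLY + CSV), the campaign
# DSM and soil mask (ESRI ASCII grids), plot delineations (GeoJSON),
# ultrasonic voltages and the manual reference table (CSV). Everything
# downstream (02-04) recomputes from code; these files document the formats
# and give the file-based entry points something real to read.

suppressPackageStartupMessages(library(canopyscan))

out <- "results/artifacts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42

scene <- generate_field_scene(
  scene_config(n_plots = 100, height_range = c(0.5, 0.8)), seed = seed)
message(sprintf("field: %d plots, true heights %.2f-%.2f m",
                scene$n_plots, min(scene$true_height), max(scene$true_height)))

# one static scan over plots 1-3, cart tilted as it would sit on rough ground
pose <- scan_pose(roll = 2.5, pitch = -1.8, yaw = 0.7, sensor_height = 2)
scan <- simulate_lidar_scan(scene, pose, c(1, 2, 3), seed = seed)
write_ply(scan$cloud, file.path(out, "scan_plots_1_3.ply"))
write_cloud_csv(scan$cloud, file.path(out, "scan_plots_1_3.csv"))
utils::write.csv(scan$truth, file.path(out, "scan_ground_truth.csv"),
                 row.names = FALSE)
message(sprintf("scan: %d points, recorded true percentiles %.1f-%.1f",
                nrow(scan$cloud),
                min(scan$truth$empirical_true_percentile),
                max(scan$truth$empirical_true_percentile)))

# campaign DSM with the full photogrammetric error budget
sim <- simulate_dsm(scene, gsd = 0.05, noise_sd = 0.02,
                    mosaic_error_sd = 0.04, surface_factor = 0.93 / 1.05,
                    seed = seed)
write_asc(sim$dsm, file.path(out, "campaign_dsm.asc"))
write_asc(sim$soil_mask, file.path(out, "campaign_soil_mask.asc"))
write_plot_geojson(plot_polygons_from_scene(scene),
                   file.path(out, "plot_delineations.geojson"))
message(sprintf("DSM: %d x %d cells at %.2f m GSD, %.0f%% soil",
                nrow(sim$dsm$values), ncol(sim$dsm$values), sim$dsm$cell_size,
                100 * mean(sim$soil_mask$values)))

# ultrasonic voltages and the averaged manual reference
us <- simulate_ultrasonic(scene, scan_pose(sensor_height = 2),
                          echo_depth_percentile = 40, noise_sd = 0.05,
                          seed = seed)
utils::write.csv(us[, c("plot_id", "voltage_V", "sensor_height_m")],
                 file.path(out, "ultrasonic_readings.csv"), row.names = FALSE)
ref <- generate_reference_heights(scene, campaign = 3, seed = seed)
utils::write.csv(ref, file.path(out, "reference_heights.csv"),
                 row.names = FALSE)
message("wrote ", length(list.files(out)), " artifact files under ", out)
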