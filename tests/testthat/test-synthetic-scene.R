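# Synthetic field scenes and simulated sensor outputs.

test_that("scene generation is deterministic and validates its config", {
  cfg <- scene_config(n_plots = 100, height_range = c(0.2, 1.0))
  s1 <- generate_field_scene(cfg, seed = 7)
  s2 <- generate_field_scene(cfg, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1$true_height, 100)
  expect_true(all(s1$true_height >= 0.2 & s1$true_height <= 1.0))
  s3 <- generate_field_scene(cfg, seed = 8)
  expect_false(identical(s1$true_height, s3$true_height))

  expect_error(scene_config(plot_width = -1), "plot_width")
  expect_error(scene_config(canopy = list(cover_fraction = 1.5)),
               "cover_fraction")
  expect_error(scene_config(height_range = c(1, 0.2)), "height_range")
  expect_error(scene_config(n_plots = 3, plots_per_row = 3,
                            true_height = c(0.5, 0.6)), "true_height")
  expect_error(scan_pose(roll = 40), "roll")
  expect_error(scan_pose(sensor_height = 0), "sensor_height")
})

test_that("degenerate terrain puts all ground returns at elevation zero", {
  sc <- noisefree_scene(c(0.5, 0.7, 0.6))
  scan <- simulate_lidar_scan(sc, scan_pose(0, 0, 0, 2), c(1, 2, 3),
                              noise_sd = 0, seed = 3)
  gz <- scan$world_cloud[scan$is_ground, "z"]
  expect_true(all(abs(gz) < 1e-12))
  expect_true(all(scan$world_cloud[!scan$is_ground, "z"] > 0))
})

test_that("scan densities match the static-scan design", {
  sc <- triplet_scene()
  scan <- simulate_lidar_scan(sc, scan_pose(0, 0, 0, 2), c(1, 2, 3), seed = 1)
  counts <- table(factor(scan$truth$position[match(scan$point_plot,
                                                   scan$truth$plot_id)],
                         levels = c("side", "middle")))
  n_mid <- sum(scan$point_plot == 2)
  n_side <- sum(scan$point_plot == 1)
  expect_true(abs(n_mid - 8000) / 8000 <= 0.05)
  expect_true(abs(n_side - 6000) / 6000 <= 0.05)
  expect_identical(nrow(scan$cloud), 20000L)
  expect_error(simulate_lidar_scan(sc, scan_pose(), c(1, 2, 3),
                                   density = c(side = 5, middle = 8)),
               "fewer than 10")
  expect_error(simulate_lidar_scan(sc, scan_pose(), c(1, 3, 2)), "contiguous")
})

test_that("an untilted scan has zero least-squares slopes, pooled and on the ground subset", {
  sc <- triplet_scene()
  scan <- simulate_lidar_scan(sc, scan_pose(0, 0, 0, 2), c(1, 2, 3), seed = 11)
  w <- scan$world_cloud
  for (proj in c("xy", "xz", "yz")) {
    expect_lt(abs(fit_projection_slope(w, proj)[["slope"]]), 1e-6)
    expect_lt(abs(fit_projection_slope(unclass(w)[scan$is_ground, ],
                                       proj)[["slope"]]), 1e-6)
  }
})

test_that("the recorded percentile of each plot reproduces its true height", {
  for (s in 1:5) {
    sc <- triplet_scene(heights = c(0.5, 0.9, 0.7), seed = s)
    scan <- simulate_lidar_scan(sc, scan_pose(1, -2, 0.5, 2), c(1, 2, 3),
                                seed = 40 + s)
    for (k in 1:3) {
      sel <- scan$point_plot == scan$truth$plot_id[k]
      h <- height_at_percentile(scan$heights[sel],
                                scan$truth$empirical_true_percentile[k])
      expect_lt(abs(h - scan$truth$true_height[k]), 1e-9)
      expect_true(scan$truth$empirical_true_percentile[k] >= 0 &&
                    scan$truth$empirical_true_percentile[k] <= 100)
    }
  }
})

test_that("ultrasonic simulation inverts the calibration exactly", {
  # dense flat canopy of height h, echo from the very top, no noise
  h <- 0.62
  sc <- generate_field_scene(
    scene_config(n_plots = 1, plots_per_row = 1, true_height = h,
                 terrain = list(slope_x = 0, slope_y = 0, roughness_sd = 0),
                 canopy = list(cover_fraction = 1, height_sd_fraction = 0,
                               mean_fraction = 1, max_fraction = 1)),
    seed = 1)
  us <- simulate_ultrasonic(sc, scan_pose(0, 0, 0, 2),
                            echo_depth_percentile = 100, noise_sd = 0, seed = 2)
  tab <- ultrasonic_heights_table(us)
  expect_lt(abs(tab$height_m - h), 1e-6)
  expect_false(tab$clamped)

  # empty footprint: echo comes from the ground, height 0
  sc0 <- generate_field_scene(
    scene_config(n_plots = 1, plots_per_row = 1, true_height = 0.5,
                 terrain = list(slope_x = 0, slope_y = 0, roughness_sd = 0),
                 canopy = list(cover_fraction = 0)), seed = 1)
  us0 <- simulate_ultrasonic(sc0, scan_pose(0, 0, 0, 2), noise_sd = 0, seed = 2)
  expect_equal(ultrasonic_heights_table(us0)$height_m, 0, tolerance = 1e-9)

  # tilt lengthens the soil path beyond the sensor height: negative reading
  us_t <- simulate_ultrasonic(sc0, scan_pose(10, 0, 0, 2), noise_sd = 0, seed = 2)
  tab_t <- ultrasonic_heights_table(us_t)
  expect_lt(tab_t$height_m, 0)
  expect_true(tab_t$negative)

  expect_error(simulate_ultrasonic(sc0, scan_pose(),
                                   echo_depth_percentile = 150), "\\[0, 100\\]")
})

test_that("simulated DSMs honor their degenerate limits and are deterministic", {
  # bare field, flat, no noise: DSM identically zero, mask all soil
  bare <- generate_field_scene(
    scene_config(n_plots = 4, plots_per_row = 2, true_height = rep(0.5, 4),
                 terrain = list(slope_x = 0, slope_y = 0, roughness_sd = 0),
                 canopy = list(cover_fraction = 0)), seed = 1)
  sim <- simulate_dsm(bare, gsd = 0.1, noise_sd = 0, seed = 1)
  expect_true(all(sim$dsm$values == 0))
  expect_true(all(sim$soil_mask$values == 1))

  # full cover at height h: in-plot cells equal h
  full <- generate_field_scene(
    scene_config(n_plots = 4, plots_per_row = 2, true_height = rep(0.5, 4),
                 terrain = list(slope_x = 0, slope_y = 0, roughness_sd = 0),
                 canopy = list(cover_fraction = 1, height_sd_fraction = 0,
                               mean_fraction = 1, max_fraction = 1)), seed = 1)
  sim_f <- simulate_dsm(full, gsd = 0.1, noise_sd = 0, seed = 1)
  polys <- plot_polygons_from_scene(full)
  vals <- plot_pixel_values(sim_f$dsm, polys[[1]])
  expect_true(all(abs(vals - 0.5) < 1e-12))

  # determinism: same seed, bit-identical rasters
  sc <- triplet_scene()
  a <- simulate_dsm(sc, gsd = 0.05, noise_sd = 0.02, mosaic_error_sd = 0.04,
                    seed = 9)
  b <- simulate_dsm(sc, gsd = 0.05, noise_sd = 0.02, mosaic_error_sd = 0.04,
                    seed = 9)
  expect_identical(a$dsm$values, b$dsm$values)
  expect_identical(a$soil_mask$values, b$soil_mask$values)

  expect_error(simulate_dsm(sc, gsd = 2), "unresolvable")
})

test_that("reference heights average replicate noise around the truth", {
  sc <- noisefree_scene(c(0.4, 0.8))
  exact <- generate_reference_heights(sc, n_replicates = 3, noise_sd = 0,
                                      campaign = 1, seed = 2)
  expect_equal(exact$height_m, sc$true_height)
  expect_identical(exact$method, rep("A", 2))

  # CLT bound: mean(reference - truth) ~ N(0, sd^2 / (reps * n))
  big <- generate_field_scene(
    scene_config(n_plots = 10000, plots_per_row = 100,
                 height_range = c(0.2, 1.0)), seed = 5)
  ref <- generate_reference_heights(big, n_replicates = 3, noise_sd = 0.02,
                                    campaign = 3, seed = 6)
  expect_identical(ref$method, rep("B", 10000))
  expect_lt(abs(mean(ref$height_m - big$true_height)),
            3 * 0.02 / sqrt(3 * 10000))
})
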