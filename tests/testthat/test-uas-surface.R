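# Soil sampling, DTM interpolation and the DSM - DTM height map.

flat_raster <- function(value, nr = 20, nc = 20, cell = 0.1, role = "dsm") {
  height_raster(matrix(value, nr, nc), origin = c(0, nr * cell),
                cell_size = cell, role = role)
}

test_that("soil sampling draws the requested deterministic subset", {
  dsm <- flat_raster(1.5)
  mask_vals <- matrix(0, 20, 20)
  mask_vals[1:10, 1:10] <- 1  # 100 soil cells
  mask <- height_raster(mask_vals, origin = c(0, 2), cell_size = 0.1,
                        role = "soil_mask")
  s <- sample_soil_pixels(dsm, mask, fraction = 0.4, seed = 3)
  expect_identical(length(s$z), 40L)
  expect_true(all(mask$values[cbind(s$row, s$col)] == 1))
  s_all <- sample_soil_pixels(dsm, mask, fraction = 1, seed = 3)
  expect_identical(length(s_all$z), 100L)
  expect_identical(sample_soil_pixels(dsm, mask, 0.4, seed = 3)$row, s$row)

  expect_error(sample_soil_pixels(dsm, mask, fraction = 0), "fraction")
  empty_mask <- height_raster(matrix(0, 20, 20), origin = c(0, 2),
                              cell_size = 0.1, role = "soil_mask")
  expect_error(sample_soil_pixels(dsm, empty_mask, 0.4), "zero soil")
  small <- flat_raster(1, nr = 5, nc = 5)
  expect_error(sample_soil_pixels(small, mask, 0.4), "congruence")
})

test_that("kriging reproduces constant fields and honors its samples", {
  dsm <- flat_raster(2.25)
  mask <- flat_raster(1, role = "soil_mask")
  s <- sample_soil_pixels(dsm, mask, fraction = 0.3, seed = 5)
  dtm <- interpolate_dtm(s, dsm)
  expect_true(all(abs(dtm$values - 2.25) < 1e-9))
  expect_identical(dtm$role, "dtm")

  # interpolating property on a rough surface
  rough <- flat_raster(0)
  rough$values <- canopyscan:::with_seed(8, matrix(stats::rnorm(400, 10, 0.05),
                                                  20, 20))
  s2 <- sample_soil_pixels(rough, mask, fraction = 0.25, seed = 9)
  dtm2 <- interpolate_dtm(s2, rough)
  expect_lt(max(abs(dtm2$values[cbind(s2$row, s2$col)] - s2$z)), 1e-6)
  # the strided prediction lattice keeps the property at sampled cells
  dtm2s <- interpolate_dtm(s2, rough, stride = 4)
  expect_lt(max(abs(dtm2s$values[cbind(s2$row, s2$col)] - s2$z)), 1e-6)
})

test_that("kriging recovers a planar terrain from dense soil samples", {
  nr <- 30; nc <- 30; cell <- 0.2
  xy <- cell_centers(height_raster(matrix(0, nr, nc), c(0, nr * cell), cell))
  plane <- outer(xy$y * 0.04, xy$x * 0.03, "+") + 5
  dsm <- height_raster(plane, c(0, nr * cell), cell, role = "dsm")
  mask <- height_raster(matrix(1, nr, nc), c(0, nr * cell), cell,
                        role = "soil_mask")
  s <- sample_soil_pixels(dsm, mask, fraction = 0.4, seed = 2)
  dtm <- interpolate_dtm(s, dsm)
  expect_lt(max(abs(dtm$values - plane)), 0.01)

  expect_error(interpolate_dtm(structure(list(z = 1:3), class = "soil_sample"),
                               dsm), "at least 4")
  collinear <- structure(list(row = 1:6, col = rep(2L, 6),
                              x = rep(xy$x[2], 6), y = xy$y[1:6],
                              z = plane[1:6, 2], sampling_fraction = 1,
                              seed = 1), class = "soil_sample")
  expect_warning(dtm_c <- interpolate_dtm(collinear, dsm), "collinear")
  expect_identical(attr(dtm_c, "method"), "idw")
})

test_that("height maps subtract congruent grids and propagate nodata", {
  dsm <- flat_raster(3)
  dtm <- flat_raster(3, role = "dtm")
  hm <- height_map(dsm, dtm)
  expect_true(all(hm$values == 0))
  expect_identical(hm$role, "height_map")

  dsm2 <- flat_raster(0.8)
  dsm2$values[3, 4] <- NA
  dsm2$values[5, 5] <- -0.2 + 0  # below-terrain surface cell
  hm2 <- height_map(dsm2, flat_raster(0, role = "dtm"))
  expect_true(is.na(hm2$values[3, 4]))
  expect_equal(hm2$values[5, 5], -0.2)   # negatives preserved
  expect_identical(attr(hm2, "negative_cells"), 1L)

  shifted <- height_raster(matrix(0, 20, 20), origin = c(1, 2),
                           cell_size = 0.1, role = "dtm")
  expect_error(height_map(dsm, shifted), "congruence")
})

test_that("a noise-free scene's height map returns each plot's canopy exactly", {
  sc <- noisefree_scene(c(0.5, 0.8, 0.65))
  sim <- simulate_dsm(sc, gsd = 0.06, noise_sd = 0, seed = 4)
  samples <- sample_soil_pixels(sim$dsm, sim$soil_mask, 0.4, seed = 5)
  dtm <- interpolate_dtm(samples, sim$dsm)
  hm <- height_map(sim$dsm, dtm)
  polys <- plot_polygons_from_scene(sc)
  for (k in 1:3) {
    vals <- plot_pixel_values(hm, polys[[k]])
    expect_lt(abs(height_at_percentile(vals, 100) - sim$truth$max_canopy[k]),
              1e-6)
  }
})

test_that("DTM error on sloped noise-free terrain stays within 2 cm", {
  sc <- generate_field_scene(
    scene_config(n_plots = 6, plots_per_row = 3, true_height = rep(0.6, 6),
                 terrain = list(slope_x = 0.03, slope_y = 0.015,
                                roughness_sd = 0)),
    seed = 6)
  sim <- simulate_dsm(sc, gsd = 0.06, noise_sd = 0, seed = 7)
  samples <- sample_soil_pixels(sim$dsm, sim$soil_mask, 0.4, seed = 8)
  dtm <- interpolate_dtm(samples, sim$dsm)
  cc <- cell_centers(sim$dsm)
  truth <- outer(cc$y * sc$terrain$slope_y, cc$x * sc$terrain$slope_x, "+")
  err <- abs(dtm$values - truth)
  expect_lt(stats::quantile(err, 0.95, names = FALSE), 0.02)
})

test_that("optimal pixel percentiles recover plot heights to within the DSM noise", {
  heights <- canopyscan:::with_seed(10, stats::runif(9, 0.5, 0.9))
  sc <- generate_field_scene(
    scene_config(n_plots = 9, plots_per_row = 3, true_height = heights,
                 terrain = list(slope_x = 0.01, slope_y = 0.01,
                                roughness_sd = 0)),
    seed = 11)
  noise_sd <- 0.03
  sim <- simulate_dsm(sc, gsd = 0.05, noise_sd = noise_sd, seed = 12)
  samples <- sample_soil_pixels(sim$dsm, sim$soil_mask, 0.4, seed = 13)
  dtm <- interpolate_dtm(samples, sim$dsm)
  hm <- height_map(sim$dsm, dtm)
  lad <- uas_plot_ladders(hm, plot_polygons_from_scene(sc), step = 1)
  ref <- data.frame(plot_id = 1:9, height_m = heights)
  opt <- optimal_percentile(lad, ref)
  expect_lt(opt$rmse, 2 * noise_sd)
})

test_that("rasters round-trip through the ASCII grid format", {
  r <- flat_raster(0)
  r$values <- canopyscan:::with_seed(14, matrix(stats::rnorm(400), 20, 20))
  r$values[2, 2] <- NA
  p <- file.path(tempdir(), "dtm.asc")
  write_asc(r, p)
  back <- read_asc(p, role = "dsm")
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_equal(back$origin, r$origin)
  expect_equal(back$cell_size, r$cell_size)

  polys <- list(plot_polygon(0, 0, 1, 2, "a"), plot_polygon(1, 0, 2, 2, "b"))
  gp <- file.path(tempdir(), "plots.geojson")
  write_plot_geojson(polys, gp)
  back_p <- read_plot_geojson(gp)
  expect_identical(back_p[[1]]$plot_id, "a")
  expect_equal(back_p[[2]]$coords, polys[[2]]$coords, ignore_attr = TRUE)
})
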