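# Synthetic field scenes and simulated sensor outputs.
#
# The generator emulates a small-plot wheat breeding trial: plots of fixed
# width laid out in rows on gently sloped, rough ground, each with a true
# canopy height. Every simulated sensor product (LiDAR cloud, ultrasonic
# voltage, canopy-top DSM, manual reference height) is drawn from the same
# scene under a seed, and ground-truth records are kept so downstream stages
# have a recoverable target.

#' Scene configuration
#'
#' @param plot_width center-to-center alleyway distance, meters (default
#'   1.524, the motivating field layout).
#' @param n_plots number of plots in the field (default 100).
#' @param plots_per_row plots per field row, laid out along X (default 10).
#' @param plot_length plot extent along Y, meters.
#' @param alley_width soil alley between plot rows, meters.
#' @param canopy_width vegetated width inside each plot, meters (the rest of
#'   the plot width is bare inter-row soil).
#' @param height_range range from which per-plot true canopy heights are
#'   drawn (meters) when `true_height` is not supplied.
#' @param true_height optional explicit vector of per-plot true heights.
#' @param terrain list: `slope_x`, `slope_y` (m/m) and `roughness_sd`
#'   (meters, per-point/cell micro-relief).
#' @param canopy list: `cover_fraction` (0-1), `height_sd_fraction`
#'   (within-plot height sd as a fraction of true height),
#'   `mean_fraction` and `max_fraction` (canopy height distribution is a
#'   normal with mean `mean_fraction * h` truncated to
#'   `[0, max_fraction * h]`), `ground_fraction` (fraction of LiDAR returns
#'   that come from the ground).
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(plot_width = 1.524, n_plots = 100, plots_per_row = 10,
                         plot_length = 2.4, alley_width = 0.6,
                         canopy_width = 1.2, height_range = c(0.2, 1.0),
                         true_height = NULL,
                         terrain = list(slope_x = 0.02, slope_y = 0.01,
                                        roughness_sd = 0.01),
                         canopy = list(cover_fraction = 0.85,
                                       height_sd_fraction = 0.08,
                                       mean_fraction = 0.85,
                                       max_fraction = 1.05,
                                       ground_fraction = 0.3)) {
  terrain <- utils::modifyList(list(slope_x = 0.02, slope_y = 0.01,
                                    roughness_sd = 0.01), terrain)
  canopy <- utils::modifyList(list(cover_fraction = 0.85,
                                   height_sd_fraction = 0.08,
                                   mean_fraction = 0.85, max_fraction = 1.05,
                                   ground_fraction = 0.3), canopy)
  cfg <- list(plot_width = plot_width, n_plots = n_plots,
              plots_per_row = plots_per_row, plot_length = plot_length,
              alley_width = alley_width, canopy_width = canopy_width,
              height_range = height_range, true_height = true_height,
              terrain = terrain, canopy = canopy)
  bad <- function(field) stop("configuration error in field '", field, "'",
                              call. = FALSE)
  if (!is.numeric(plot_width) || plot_width <= 0) bad("plot_width")
  if (n_plots < 1) bad("n_plots")
  if (plots_per_row < 1 || plots_per_row > n_plots) bad("plots_per_row")
  if (plot_length <= 0) bad("plot_length")
  if (alley_width < 0) bad("alley_width")
  if (canopy_width <= 0 || canopy_width > plot_width) bad("canopy_width")
  if (is.null(true_height)) {
    if (length(height_range) != 2 || any(height_range < 0) ||
        height_range[1] > height_range[2]) bad("height_range")
  } else if (length(true_height) != n_plots || any(true_height < 0)) {
    bad("true_height")
  }
  if (canopy$cover_fraction < 0 || canopy$cover_fraction > 1) bad("canopy$cover_fraction")
  if (canopy$height_sd_fraction < 0) bad("canopy$height_sd_fraction")
  if (canopy$ground_fraction < 0 || canopy$ground_fraction > 1) bad("canopy$ground_fraction")
  if (terrain$roughness_sd < 0) bad("terrain$roughness_sd")
  cfg
}

#' Scan pose of the phenocart sensor bar
#'
#' @param roll,pitch,yaw tilt angles in degrees (each within +/-30, the
#'   simulation bound).
#' @param sensor_height sensor height above the soil surface, meters (> 0).
#' @return a `scan_pose` list.
#' @export
scan_pose <- function(roll = 0, pitch = 0, yaw = 0, sensor_height = 2) {
  if (any(abs(c(roll, pitch, yaw)) > 30)) {
    stop("configuration error in field 'roll/pitch/yaw': |angle| must be <= 30 deg",
         call. = FALSE)
  }
  if (sensor_height <= 0) {
    stop("configuration error in field 'sensor_height'", call. = FALSE)
  }
  structure(list(roll = roll, pitch = pitch, yaw = yaw,
                 sensor_height = sensor_height), class = "scan_pose")
}

# World rotation applied by a pose: Rz(yaw) %*% Ry(pitch) %*% Rx(roll).
pose_rotation <- function(pose) {
  rot_z(pose$yaw) %*% rot_y(pose$pitch) %*% rot_x(pose$roll)
}

#' Generate a synthetic field scene
#'
#' Draws per-plot true canopy heights (uniform over `height_range` unless
#' supplied) and fixes the field layout and terrain. Deterministic under
#' (config, seed).
#'
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return a `field_scene` list: the config plus `true_height`, `seed` and a
#'   `plots` data.frame (plot_id, row, col, center_x, center_y).
#' @export
generate_field_scene <- function(config = scene_config(), seed = 1) {
  n <- config$n_plots
  th <- config$true_height
  if (is.null(th)) {
    th <- with_seed(seed, stats::runif(n, config$height_range[1],
                                       config$height_range[2]))
  }
  row_pitch <- config$plot_length + config$alley_width
  idx <- seq_len(n) - 1L
  plots <- data.frame(
    plot_id = seq_len(n),
    row = idx %/% config$plots_per_row + 1L,
    col = idx %% config$plots_per_row + 1L)
  plots$center_x <- (plots$col - 0.5) * config$plot_width
  plots$center_y <- (plots$row - 0.5) * row_pitch
  scene <- c(config, list(true_height = NULL))
  scene$true_height <- th
  scene$seed <- seed
  scene$plots <- plots
  scene$row_pitch <- row_pitch
  class(scene) <- "field_scene"
  scene
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene: %d plots (%d per row), plot_width=%g m, heights %.2f-%.2f m, seed=%d>\n",
              x$n_plots, x$plots_per_row, x$plot_width,
              min(x$true_height), max(x$true_height), x$seed))
  invisible(x)
}

# Smooth terrain elevation (without micro-relief) at field coordinates.
terrain_elevation <- function(scene, x, y) {
  scene$terrain$slope_x * x + scene$terrain$slope_y * y
}

# Draw within-plot canopy heights for a plot of true height h: normal with
# mean mean_fraction*h and sd height_sd_fraction*h, truncated to
# [0, max_fraction*h]. The upper truncation just above h gives a realistic
# thin upper tail, so the true height sits below the 100th percentile.
draw_canopy_heights <- function(n, h, canopy) {
  if (h <= 0) return(rep(0, n))
  rtruncnorm(n, mean = canopy$mean_fraction * h,
             sd = canopy$height_sd_fraction * h,
             lower = 0, upper = canopy$max_fraction * h)
}

# Analytic mean of the truncated-normal canopy height distribution.
canopy_mean_height <- function(h, canopy) {
  if (h <= 0) return(0)
  mu <- canopy$mean_fraction * h
  sd <- canopy$height_sd_fraction * h
  if (sd <= 0) return(min(mu, canopy$max_fraction * h))
  a <- (0 - mu) / sd
  b <- (canopy$max_fraction * h - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Simulate one static LiDAR scan over three adjacent plots
#'
#' The sensor sits `sensor_height` above the center of the middle plot.
#' Ground returns lie on the (sloped, rough) terrain; canopy returns add
#' above-ground heights drawn from the plot's truncated-normal canopy
#' distribution. World-frame points are mapped to the sensor frame by the
#' pose rotation `Rz(yaw) Ry(pitch) Rx(roll)` followed by the sensor-height
#' translation. For each plot the scan records the continuous percentile at
#' which the plot's true height sits within the generated above-ground
#' height set, making percentile recovery self-verifying downstream.
#'
#' The random components of the scan (micro-relief, ranging noise and the
#' within-plot canopy height deviations around each plot's analytic mean)
#' are orthogonalized against the plot coordinates: the ground subset and
#' the pooled cloud both have exactly zero least-squares slopes in all
#' three coordinate-plane projections before the pose is applied, up to the
#' real between-plot canopy structure. The untilted scene therefore carries
#' no spurious sampling tilt, making the applied pose exactly identifiable
#' by the downstream tilt correction; what remains confounded with tilt is
#' only the genuine cross-plot height structure (and the terrain slope),
#' as in the field.
#'
#' @param scene a `field_scene`.
#' @param pose a [scan_pose()].
#' @param plot_ids three contiguous plot ids within one field row; the
#'   middle one is the middle plot (default `c(1, 2, 3)`).
#' @param density points per plot: named vector with `side` and `middle`
#'   counts (defaults 6000 and 8000, typical of a static scan where the
#'   middle plot sits directly under the sensor).
#' @param noise_sd LiDAR ranging noise on Z, meters (default 0.005).
#' @param seed integer seed.
#' @return list: `cloud` (sensor-frame `point_cloud`, `frame_state = "raw"`),
#'   `truth` (data.frame plot_id, position, true_height,
#'   empirical_true_percentile), `world_cloud` (the untilted world-frame
#'   cloud), `heights` (per-point above-plane height), `point_plot` (per-point
#'   plot id), `is_ground` (per-point ground/canopy flag), `pose`.
#' @export
simulate_lidar_scan <- function(scene, pose = scan_pose(),
                                plot_ids = c(1, 2, 3),
                                density = c(side = 6000, middle = 8000),
                                noise_sd = 0.005, seed = 1) {
  stopifnot(inherits(scene, "field_scene"))
  if (length(plot_ids) != 3L) {
    stop("a static scan covers exactly 3 contiguous plots", call. = FALSE)
  }
  pl <- scene$plots[match(plot_ids, scene$plots$plot_id), ]
  if (anyNA(pl$plot_id) || length(unique(pl$row)) != 1L ||
      !all(diff(pl$col) == 1)) {
    stop("plot_ids must be 3 contiguous plots within one field row, in left-middle-right order",
         call. = FALSE)
  }
  if (any(density < 10)) {
    stop("generation error: density gives a plot fewer than 10 points", call. = FALSE)
  }
  mid <- pl[2, ]
  w <- scene$plot_width
  positions <- c("side", "middle", "side")
  with_seed(seed, {
    xs <- ys <- us <- ms <- list()
    is_ground <- list()
    point_plot <- list()
    for (k in 1:3) {
      n <- round(unname(density[positions[k]]))
      h_true <- scene$true_height[pl$plot_id[k]]
      n_ground <- round(scene$canopy$ground_fraction * n)
      n_canopy <- n - n_ground
      # scan-local coordinates: origin on the ground under the sensor
      x0 <- pl$center_x[k] - mid$center_x
      # uniform area samples, recentered (and minimally rescaled so no
      # point leaves its design rectangle) to their design means, so the
      # canopy/ground group means carry no sampling offset and the scene's
      # apparent tilt equals exactly the applied pose
      recenter <- function(v, target, half) {
        if (!length(v)) return(v)
        d <- v - mean(v)
        mx <- max(abs(d))
        if (mx > half) d <- d * (half / mx)
        target + d
      }
      gx <- recenter(stats::runif(n_ground, x0 - w / 2, x0 + w / 2), x0, w / 2)
      gy <- recenter(stats::runif(n_ground, -scene$plot_length / 2,
                                  scene$plot_length / 2), 0, scene$plot_length / 2)
      cw <- scene$canopy_width
      cx <- recenter(stats::runif(n_canopy, x0 - cw / 2, x0 + cw / 2), x0, cw / 2)
      cy <- recenter(stats::runif(n_canopy, -scene$plot_length / 2,
                                  scene$plot_length / 2), 0, scene$plot_length / 2)
      mk <- canopy_mean_height(h_true, scene$canopy)
      ch <- draw_canopy_heights(n_canopy, h_true, scene$canopy)
      micro <- stats::rnorm(n, 0, scene$terrain$roughness_sd)
      noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
      xs[[k]] <- c(gx, cx); ys[[k]] <- c(gy, cy)
      # noise component: full height for ground, deviation from the plot's
      # analytic canopy mean for canopy points
      us[[k]] <- c(micro[seq_len(n_ground)],
                   ch - mk + micro[n_ground + seq_len(n_canopy)]) + noise
      ms[[k]] <- c(rep(0, n_ground), rep(mk, n_canopy))
      is_ground[[k]] <- c(rep(TRUE, n_ground), rep(FALSE, n_canopy))
      point_plot[[k]] <- rep(pl$plot_id[k], n)
    }
    x <- unlist(xs); y <- unlist(ys); u <- unlist(us); m <- unlist(ms)
    g <- unlist(is_ground)
    point_plot <- unlist(point_plot)
    o <- orthogonalize_scan_noise(x, y, u, g)
    h_final <- o$u + m
    plane <- scene$terrain$slope_x * o$x + scene$terrain$slope_y * o$y
    xyz_world <- cbind(x = o$x, y = o$y, z = plane + h_final)
    truth <- do.call(rbind, lapply(1:3, function(k) {
      sel <- point_plot == pl$plot_id[k]
      data.frame(plot_id = pl$plot_id[k], position = positions[k],
                 true_height = scene$true_height[pl$plot_id[k]],
                 empirical_true_percentile =
                   percentile_of_height(h_final[sel],
                                        scene$true_height[pl$plot_id[k]]))
    }))
    R <- pose_rotation(pose)
    xyz_sensor <- t(R %*% t(xyz_world))
    xyz_sensor[, 3] <- xyz_sensor[, 3] - pose$sensor_height
    list(cloud = point_cloud(xyz_sensor, "raw"),
         truth = truth,
         world_cloud = point_cloud(xyz_world, "raw"),
         heights = h_final,
         point_plot = point_plot,
         is_ground = g,
         pose = pose)
  })
}

# Remove the empirical sampling tilt of a generated scan: after this, the
# ground subset has exactly zero least-squares slopes in the x-y, x-z and
# y-z projections, and so does the pooled cloud's noise component (the real
# between-plot canopy structure carried in the plot means is left intact).
# All adjustments are slope removals of order sd/sqrt(n) — sub-millimeter
# shifts — applied to the canopy points' coordinates/noise so that the
# ground corrections are not disturbed.
orthogonalize_scan_noise <- function(x, y, u, g) {
  c_ <- !g
  if (sum(g) < 3 || sum(c_) < 3) return(list(x = x, y = y, u = u))
  # 1. ground: zero the y-on-x slope
  bg <- stats::cov(x[g], y[g]) / stats::var(x[g])
  y[g] <- y[g] - bg * (x[g] - mean(x[g]))
  # 2. canopy: zero the pooled x-y covariance (centered, keeps means)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  axx <- sum((x[c_] - mean(x)) * (x[c_] - mean(x[c_])))
  if (abs(axx) > 1e-12) y[c_] <- y[c_] - (sxy / axx) * (x[c_] - mean(x[c_]))
  # 3. ground: zero both z slopes jointly (x-y already orthogonal on ground)
  fitg <- stats::lm.fit(cbind(1, x[g] - mean(x[g]), y[g] - mean(y[g])),
                        u[g])$coefficients
  u[g] <- u[g] - fitg[2] * (x[g] - mean(x[g])) - fitg[3] * (y[g] - mean(y[g]))
  # 4. canopy: zero the pooled x-z and y-z noise covariances (2x2 solve)
  xc <- x[c_] - mean(x[c_]); yc <- y[c_] - mean(y[c_])
  xa <- x - mean(x); ya <- y - mean(y)
  A <- matrix(c(sum(xa[c_] * xc), sum(xa[c_] * yc),
                sum(ya[c_] * xc), sum(ya[c_] * yc)), 2, 2, byrow = TRUE)
  b <- c(sum(xa * u), sum(ya * u))
  if (abs(det(A)) > 1e-12) {
    bc <- solve(A, b)
    u[c_] <- u[c_] - bc[1] * xc - bc[2] * yc
  }
  list(x = x, y = y, u = u)
}

#' Simulate static ultrasonic readings over plots
#'
#' The sensor looks straight down from `sensor_height` over each plot center
#' with a cone of half-angle 7 degrees. The echo comes from the
#' `echo_depth_percentile`-th percentile of the canopy heights inside the
#' footprint — the sound wave penetrates sparse upper canopy and reflects
#' from denser vegetation lower down, so small percentiles model deep echo
#' penetration. An empty footprint echoes from the ground. Cart tilt
#' lengthens the path by `1 / cos(tilt)`, which is how distances exceeding
#' the sensor height (hence negative canopy heights) arise. The returned
#' voltage is the exact inverse of the lab calibration, so converting it
#' back reproduces the simulated distance.
#'
#' @param scene a `field_scene`.
#' @param pose a single [scan_pose()] applied to every plot, or a list of
#'   one pose per plot.
#' @param plot_ids plots to read (default all).
#' @param echo_depth_percentile percentile (0-100) of footprint canopy
#'   heights the echo returns from.
#' @param noise_sd echo distance noise, meters.
#' @param footprint_density canopy elements per square meter available as
#'   reflectors within the footprint.
#' @param coeffs calibration coefficients, see [calibration_coefficients()].
#' @param unit_scale meters per calibration distance unit (see
#'   [ultrasonic_height()]).
#' @param seed integer seed.
#' @return data.frame: plot_id, voltage_V, sensor_height_m,
#'   simulated_distance (in calibration units), clamped (logical; TRUE when
#'   the voltage hit the 0-10 V rail).
#' @export
simulate_ultrasonic <- function(scene, pose = scan_pose(), plot_ids = NULL,
                                echo_depth_percentile = 30, noise_sd = 0.05,
                                footprint_density = 300,
                                coeffs = calibration_coefficients(),
                                unit_scale = 0.01, seed = 1) {
  stopifnot(inherits(scene, "field_scene"))
  if (echo_depth_percentile < 0 || echo_depth_percentile > 100) {
    stop("echo_depth_percentile must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(plot_ids)) plot_ids <- scene$plots$plot_id
  poses <- if (inherits(pose, "scan_pose")) rep(list(pose), length(plot_ids)) else pose
  if (length(poses) != length(plot_ids)) {
    stop("pose must be one scan_pose or a list of one per plot", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(seq_along(plot_ids), function(i) {
      p <- poses[[i]]
      hs <- p$sensor_height
      R <- pose_rotation(p)
      cos_tilt <- max(R[3, 3], 1e-6)  # sensor axis vs vertical
      h_true <- scene$true_height[plot_ids[i]]
      area <- pi * (hs * tan(deg2rad(7)))^2
      lambda <- footprint_density * area * scene$canopy$cover_fraction
      n_fp <- stats::rpois(1, lambda)
      if (n_fp == 0 || h_true <= 0) {
        d_m <- hs / cos_tilt  # ground echo
      } else {
        ch <- draw_canopy_heights(n_fp, h_true, scene$canopy)
        q <- height_at_percentile(ch, echo_depth_percentile)
        d_m <- (hs - q) / cos_tilt
      }
      if (noise_sd > 0) d_m <- d_m + stats::rnorm(1, 0, noise_sd)
      d_units <- d_m / unit_scale
      v <- (d_units - coeffs$intercept) / coeffs$slope
      clamped <- v < 0 || v > 10
      data.frame(plot_id = plot_ids[i], voltage_V = min(max(v, 0), 10),
                 sensor_height_m = hs, simulated_distance = d_units,
                 clamped = clamped)
    })
    do.call(rbind, out)
  })
}

#' Simulate a canopy-top DSM and soil mask
#'
#' Each cell carries the terrain elevation plus, where the cell falls on
#' vegetated plot area and the canopy covers it, a canopy height drawn from
#' the plot's truncated-normal distribution (the photogrammetric surface
#' follows the locally tallest foliage). Bare cells form the soil mask.
#' Optionally a smooth correlated error field emulates photogrammetric
#' mosaic/georeferencing error — the error component that survives per-plot
#' aggregation — in addition to iid cell noise.
#'
#' `surface_factor` models the resolution limit of the camera: thin
#' structures (wheat spikes after heading) are not resolved in the imagery,
#' so the photogrammetric surface tracks the leaf canopy below them. The
#' generated canopy surface heights are scaled by this factor (1 = the
#' surface sees the full canopy; values below 1 emulate the growing
#' underestimation of reproductive-stage height maps).
#'
#' @param scene a `field_scene`.
#' @param gsd ground sampling distance, meters per pixel (must resolve the
#'   plots: `gsd <= plot_width`).
#' @param noise_sd cell noise sd, meters. Photogrammetric surface error is
#'   locally correlated (dense-matching and mesh interpolation smooth over
#'   neighboring cells), so the noise field is generated at `noise_scale`
#'   patch resolution and interpolated; `noise_scale = 0` gives iid noise.
#' @param noise_scale correlation length of the cell noise, meters
#'   (default 0.25).
#' @param mosaic_error_sd sd of the smooth correlated error field, meters
#'   (0 disables it).
#' @param mosaic_scale correlation length of the smooth field, meters.
#' @param surface_factor fraction of the canopy height visible to the
#'   photogrammetric surface (default 1).
#' @param seed integer seed.
#' @return list: `dsm` (`height_raster`, role dsm), `soil_mask`
#'   (`height_raster`, role soil_mask, 1 = soil), `truth` (data.frame
#'   plot_id, true_height, max_canopy — the tallest generated canopy cell of
#'   the plot).
#' @export
simulate_dsm <- function(scene, gsd = 0.05, noise_sd = 0.02,
                         noise_scale = 0.25, mosaic_error_sd = 0,
                         mosaic_scale = 3, surface_factor = 1, seed = 1) {
  stopifnot(inherits(scene, "field_scene"))
  if (gsd > scene$plot_width) {
    stop("gsd larger than plot_width: plots are unresolvable", call. = FALSE)
  }
  xmax <- scene$plots_per_row * scene$plot_width
  nrows_field <- max(scene$plots$row)
  ymax <- nrows_field * scene$row_pitch
  nc <- ceiling(xmax / gsd)
  nr <- ceiling(ymax / gsd)
  origin <- c(0, nr * gsd)
  with_seed(seed, {
    xc <- (seq_len(nc) - 0.5) * gsd
    yc <- origin[2] - (seq_len(nr) - 0.5) * gsd
    terr <- outer(yc * scene$terrain$slope_y, xc * scene$terrain$slope_x, "+")
    if (scene$terrain$roughness_sd > 0) {
      terr <- terr + matrix(stats::rnorm(nr * nc, 0, scene$terrain$roughness_sd), nr, nc)
    }
    canopy <- matrix(0, nr, nc)
    truth <- scene$plots[, "plot_id", drop = FALSE]
    truth$true_height <- scene$true_height
    truth$max_canopy <- 0
    for (i in seq_len(nrow(scene$plots))) {
      p <- scene$plots[i, ]
      h <- scene$true_height[p$plot_id]
      cw <- scene$canopy_width
      cols <- which(xc >= p$center_x - cw / 2 & xc <= p$center_x + cw / 2)
      rows <- which(yc >= p$center_y - scene$plot_length / 2 &
                      yc <= p$center_y + scene$plot_length / 2)
      if (!length(cols) || !length(rows) || h <= 0) next
      ncell <- length(rows) * length(cols)
      covered <- stats::runif(ncell) < scene$canopy$cover_fraction
      hc <- numeric(ncell)
      hc[covered] <- surface_factor *
        draw_canopy_heights(sum(covered), h, scene$canopy)
      canopy[rows, cols] <- matrix(hc, length(rows), length(cols))
      if (any(covered)) truth$max_canopy[i] <- max(hc)
    }
    dsm_vals <- terr + canopy
    if (mosaic_error_sd > 0) {
      dsm_vals <- dsm_vals + smooth_error_field(nr, nc, gsd, mosaic_error_sd,
                                                mosaic_scale)
    }
    if (noise_sd > 0) {
      dsm_vals <- dsm_vals + if (noise_scale > 0) {
        smooth_error_field(nr, nc, gsd, noise_sd, noise_scale)
      } else {
        matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
    }
    list(dsm = height_raster(dsm_vals, origin, gsd, role = "dsm"),
         soil_mask = height_raster((canopy == 0) * 1, origin, gsd,
                                   role = "soil_mask"),
         truth = truth)
  })
}

# Smooth correlated error field: white noise on a coarse grid of spacing
# `scale` meters, bilinearly interpolated to the raster grid.
smooth_error_field <- function(nr, nc, gsd, sd, scale) {
  step <- max(1L, round(scale / gsd))
  cr <- seq(1, nr + step, by = step)
  cc <- seq(1, nc + step, by = step)
  coarse <- matrix(stats::rnorm(length(cr) * length(cc), 0, sd),
                   length(cr), length(cc))
  ri <- pmin((seq_len(nr) - 1) / step + 1, length(cr) - 1e-9)
  ci <- pmin((seq_len(nc) - 1) / step + 1, length(cc) - 1e-9)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  a <- coarse[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- coarse[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  d <- coarse[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  e <- coarse[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  w_fr <- rep(fr, nc); w_fc <- rep(fc, each = nr)
  matrix((1 - w_fr) * (1 - w_fc) * a + (1 - w_fr) * w_fc * b +
           w_fr * (1 - w_fc) * d + w_fr * w_fc * e, nr, nc)
}

#' Generate manual reference heights
#'
#' Per plot, the mean of `n_replicates` noisy yardstick measurements around
#' the true height (three measurements averaged is the motivating field
#' protocol).
#'
#' @param scene a `field_scene`.
#' @param n_replicates measurements averaged per plot (>= 1, default 3).
#' @param noise_sd per-measurement sd, meters.
#' @param campaign campaign index label to attach.
#' @param method manual method label (`"A"` top-of-stem / `"B"`
#'   top-of-spike); defaults from [campaign_method()] when `campaign` given.
#' @param seed integer seed.
#' @return data.frame: plot_id, campaign, method, height_m.
#' @export
generate_reference_heights <- function(scene, n_replicates = 3,
                                       noise_sd = 0.02, campaign = NA,
                                       method = NULL, seed = 1) {
  stopifnot(inherits(scene, "field_scene"))
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (is.null(method)) {
    method <- if (is.na(campaign)) NA_character_ else campaign_method(campaign)
  }
  with_seed(seed, {
    n <- scene$n_plots
    draws <- matrix(stats::rnorm(n * n_replicates, 0, noise_sd), n, n_replicates)
    data.frame(plot_id = scene$plots$plot_id, campaign = campaign,
               method = method,
               height_m = scene$true_height + rowMeans(draws))
  })
}

#' Plot delineation polygons of a scene
#'
#' Rectangles over each plot's vegetated area, the zonal footprints used for
#' per-plot pixel percentiles.
#'
#' @param scene a `field_scene`.
#' @return list of polygons (see [plot_polygon()]).
#' @export
plot_polygons_from_scene <- function(scene) {
  lapply(seq_len(nrow(scene$plots)), function(i) {
    p <- scene$plots[i, ]
    plot_polygon(p$center_x - scene$canopy_width / 2,
                 p$center_y - scene$plot_length / 2,
                 p$center_x + scene$canopy_width / 2,
                 p$center_y + scene$plot_length / 2,
                 plot_id = p$plot_id)
  })
}
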