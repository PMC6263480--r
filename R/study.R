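# End-to-end synthetic sensor-comparison study: simulate five campaigns over
# one field, run the LiDAR, ultrasonic and UAS pipelines, and evaluate.

#' Study configuration
#'
#' Defaults emulate the motivating field trial: 100 plots measured in five
#' campaigns (methods A, A, B, B, B), canopy growing between campaigns,
#' static LiDAR scans of three plots (about 6000 points per side plot and
#' 8000 per middle plot), a downward ultrasonic sensor whose echo comes from
#' deeper in the canopy as plants mature (leaf tops early, lower canopy once
#' spikes emerge), and a per-campaign DSM at 5 cm ground sampling distance
#' with 40% of soil pixels kriged into a DTM. Sensor noise magnitudes are
#' set so each modality's synthetic error budget matches the order of
#' magnitude field studies report for it (see the methods vignette).
#'
#' @param n_plots plots in the field.
#' @param plots_per_row plots per field row.
#' @param n_campaigns number of campaigns (up to 5).
#' @param growth per-campaign fraction of each plot's potential height.
#' @param potential_range range of per-plot potential (mature) heights, m.
#' @param pose_sd sd of roll/pitch/yaw across scans, degrees (clamped to
#'   +/-10).
#' @param sensor_height LiDAR/ultrasonic mounting height, m.
#' @param lidar_density points per plot by position (side/middle).
#' @param lidar_noise_sd LiDAR Z noise, m.
#' @param baseline_strategy ground-baseline strategy for the LiDAR pipeline.
#' @param echo_depth_percentiles per-campaign ultrasonic echo percentile.
#' @param ultrasonic_noise_sd echo distance noise, m.
#' @param unit_scale calibration unit scale (see [ultrasonic_height()]).
#' @param gsd DSM ground sampling distance, m.
#' @param dsm_noise_sd DSM cell noise, m.
#' @param dsm_noise_scale correlation length of the DSM cell noise, m.
#' @param mosaic_error_sd smooth correlated DSM error, m.
#' @param uas_surface_factors per-campaign fraction of the true plot height
#'   visible to the photogrammetric surface (spikes are invisible to the
#'   camera after heading, so the fraction drops below 1 from the boot
#'   stage on and the height map tops out at leaf level).
#' @param soil_fraction fraction of soil pixels sampled for the DTM.
#' @param dtm_method `"kriging"` or `"idw"`.
#' @param dtm_stride prediction-lattice stride for the DTM (cells).
#' @param reference_noise_sd per-replicate manual measurement noise, m.
#' @param reference_replicates manual measurements averaged per plot.
#' @param scene overrides passed to [scene_config()] (list).
#' @return a `study_config` list.
#' @export
study_config <- function(n_plots = 100, plots_per_row = 10, n_campaigns = 5,
                         growth = c(0.35, 0.55, 0.75, 0.9, 1.0),
                         potential_range = c(0.7, 1.1),
                         pose_sd = 3, sensor_height = 2,
                         lidar_density = c(side = 6000, middle = 8000),
                         lidar_noise_sd = 0.005,
                         baseline_strategy = "histogram_peak",
                         echo_depth_percentiles = c(100, 60, 40, 30, 25),
                         ultrasonic_noise_sd = 0.05,
                         unit_scale = 0.01,
                         gsd = 0.05, dsm_noise_sd = 0.02,
                         dsm_noise_scale = 0.25,
                         mosaic_error_sd = 0.04,
                         uas_surface_factors = c(1, 1, 0.93, 0.91, 0.89),
                         soil_fraction = 0.4, dtm_method = "kriging",
                         dtm_stride = 4L,
                         reference_noise_sd = 0.02,
                         reference_replicates = 3,
                         scene = list()) {
  if (n_campaigns < 1 || n_campaigns > 5) {
    stop("n_campaigns must be in 1..5", call. = FALSE)
  }
  list(n_plots = n_plots, plots_per_row = plots_per_row,
       n_campaigns = n_campaigns,
       growth = growth[seq_len(n_campaigns)],
       potential_range = potential_range,
       pose_sd = pose_sd, sensor_height = sensor_height,
       lidar_density = lidar_density, lidar_noise_sd = lidar_noise_sd,
       baseline_strategy = baseline_strategy,
       echo_depth_percentiles = echo_depth_percentiles[seq_len(n_campaigns)],
       ultrasonic_noise_sd = ultrasonic_noise_sd, unit_scale = unit_scale,
       gsd = gsd, dsm_noise_sd = dsm_noise_sd,
       dsm_noise_scale = dsm_noise_scale,
       mosaic_error_sd = mosaic_error_sd,
       uas_surface_factors = uas_surface_factors[seq_len(n_campaigns)],
       soil_fraction = soil_fraction, dtm_method = dtm_method,
       dtm_stride = dtm_stride,
       reference_noise_sd = reference_noise_sd,
       reference_replicates = reference_replicates,
       scene = scene)
}

# Triplet scan plan for one field row of k plots: scans centered on plots
# 2, 5, 8, ... and, when the row length is not a multiple of 3, a final
# scan centered on the second-to-last plot to pick up the remainder as side
# plots. Returns a list of lists (plot_ids, new = ids whose first estimate
# comes from this scan).
row_scan_plan <- function(cols) {
  k <- length(cols)
  centers <- seq(2, k - 1, by = 3)
  if (k %% 3 != 0) centers <- unique(c(centers, k - 1))
  plan <- list()
  seen <- integer(0)
  for (c0 in centers) {
    ids <- cols[(c0 - 1):(c0 + 1)]
    plan[[length(plan) + 1]] <- list(plot_ids = ids,
                                     new = setdiff(ids, seen))
    seen <- union(seen, ids)
  }
  plan
}

#' Run the LiDAR pipeline on one scan cloud
#'
#' trim -> tilt-correct -> ground baseline -> split -> per-plot 0.5%-step
#' ladders. Also produces ladders from the uncorrected (raw) cloud with the
#' same baseline strategy, for the raw-versus-processed comparison.
#'
#' @param cloud a raw sensor-frame `point_cloud` from one static scan.
#' @param plot_ids the three plot ids (left, middle, right).
#' @param plot_width plot width, m.
#' @param sensor_height sensor height, m (baseline fallback and
#'   `sensor_height` strategy).
#' @param baseline_strategy see [correct_ground_baseline()].
#' @param keep ids (subset of `plot_ids`) for which ladders are returned.
#' @return list: `ladders`, `raw_ladders` (data.frames plot_id, position,
#'   percentile, height), `tilt` (the `tilt_estimate`), `baseline`.
#' @export
process_scan <- function(cloud, plot_ids, plot_width = 1.524,
                         sensor_height = 2,
                         baseline_strategy = "histogram_peak",
                         keep = plot_ids) {
  trimmed <- trim_cloud(cloud, plot_width)
  tc <- correct_tilt(trimmed)
  gb <- correct_ground_baseline(tc$cloud, baseline_strategy,
                                sensor_height = sensor_height)
  gb_raw <- correct_ground_baseline(set_frame_state(trimmed, "corrected"),
                                    baseline_strategy,
                                    sensor_height = sensor_height)
  lad <- function(corrected, which_ids) {
    parts <- split_cloud(corrected, plot_width)
    out <- lapply(1:3, function(k) {
      if (!plot_ids[k] %in% which_ids) return(NULL)
      part <- parts[[k]]
      if (nrow(part) < 10) {
        stop("plot ", plot_ids[k], " received fewer than 10 points", call. = FALSE)
      }
      cbind(data.frame(plot_id = plot_ids[k],
                       position = attr(part, "position")),
            percentile_ladder(part[, "z"], step = 0.5, source = "lidar",
                              plot_id = plot_ids[k]))
    })
    do.call(rbind, out)
  }
  list(ladders = lad(gb$cloud, keep),
       raw_ladders = lad(gb_raw$cloud, keep),
       tilt = tc$estimate, baseline = gb$baseline)
}

#' Run the full synthetic sensor-comparison study
#'
#' Simulates one field over `n_campaigns` campaigns and, per campaign, runs
#' the three sensor pipelines: static LiDAR scans processed into per-plot
#' percentile ladders (raw and tilt-corrected), ultrasonic voltages
#' converted through the calibration, and a DSM kriged into a DTM whose
#' difference yields per-plot pixel ladders. All randomness derives from
#' `seed`; identical (config, seed) reproduce the study bit for bit.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @param progress emit per-campaign progress messages.
#' @return a `simulation_study` list: `ladders`, `raw_ladders`,
#'   `uas_ladders`, `ultrasonic`, `reference`, `truth` (per plot-campaign
#'   ground truth), `report` (the [build_comparison_report()] output),
#'   `config`, `seed`.
#' @export
run_simulation_study <- function(config = study_config(), seed = 1,
                                 progress = FALSE) {
  potential <- with_seed(derive_seed(seed, 1),
                         stats::runif(config$n_plots, config$potential_range[1],
                                      config$potential_range[2]))
  ladders <- raw_ladders <- uas_ladders <- list()
  ultrasonic <- reference <- truth <- list()
  for (cmp in seq_len(config$n_campaigns)) {
    if (progress) message("campaign ", cmp)
    sc_args <- utils::modifyList(
      list(n_plots = config$n_plots, plots_per_row = config$plots_per_row,
           true_height = potential * config$growth[cmp]),
      config$scene)
    scene <- generate_field_scene(do.call(scene_config, sc_args),
                                  seed = derive_seed(seed, 100 + cmp))
    # --- LiDAR: static scans over triplets, row by row ---
    rows <- split(scene$plots, scene$plots$row)
    scan_i <- 0L
    camp_truth <- list()
    for (rw in rows) {
      plan <- row_scan_plan(rw$plot_id)
      for (sp in plan) {
        scan_i <- scan_i + 1L
        pose_seed <- derive_seed(seed, 100000 + 100 * cmp + scan_i)
        ang <- with_seed(pose_seed,
                         pmin(10, pmax(-10, stats::rnorm(3, 0, config$pose_sd))))
        pose <- scan_pose(ang[1], ang[2], ang[3], config$sensor_height)
        scan <- simulate_lidar_scan(scene, pose, sp$plot_ids,
                                    density = config$lidar_density,
                                    noise_sd = config$lidar_noise_sd,
                                    seed = derive_seed(seed, 200000 + 100 * cmp + scan_i))
        pr <- process_scan(scan$cloud, sp$plot_ids,
                           plot_width = scene$plot_width,
                           sensor_height = config$sensor_height,
                           baseline_strategy = config$baseline_strategy,
                           keep = sp$new)
        ladders[[length(ladders) + 1]] <- cbind(campaign = cmp, pr$ladders)
        raw_ladders[[length(raw_ladders) + 1]] <- cbind(campaign = cmp,
                                                        pr$raw_ladders)
        tr <- scan$truth[scan$truth$plot_id %in% sp$new, ]
        camp_truth[[length(camp_truth) + 1]] <- cbind(campaign = cmp, tr)
      }
    }
    truth[[cmp]] <- do.call(rbind, camp_truth)
    # --- Ultrasonic: one static reading per plot ---
    us_pose_seed <- derive_seed(seed, 3000 + cmp)
    us_angles <- with_seed(us_pose_seed,
                           matrix(pmin(10, pmax(-10, stats::rnorm(3 * config$n_plots, 0, config$pose_sd))),
                                  ncol = 3))
    poses <- lapply(seq_len(config$n_plots), function(i)
      scan_pose(us_angles[i, 1], us_angles[i, 2], us_angles[i, 3],
                config$sensor_height))
    us <- simulate_ultrasonic(scene, poses,
                              echo_depth_percentile = config$echo_depth_percentiles[cmp],
                              noise_sd = config$ultrasonic_noise_sd,
                              unit_scale = config$unit_scale,
                              seed = derive_seed(seed, 4000 + cmp))
    us_h <- ultrasonic_heights_table(us, unit_scale = config$unit_scale)
    ultrasonic[[cmp]] <- data.frame(plot_id = us_h$plot_id, campaign = cmp,
                                    height_m = us_h$height_m,
                                    negative = us_h$negative)
    # --- UAS: DSM -> soil samples -> kriged DTM -> height map -> ladders ---
    # uas_surface_factors is the visible fraction of the *true* height; the
    # canopy draw tops out at max_fraction * h, so rescale accordingly
    sf <- config$uas_surface_factors[cmp] / scene$canopy$max_fraction
    sim <- simulate_dsm(scene, gsd = config$gsd,
                        noise_sd = config$dsm_noise_sd,
                        noise_scale = config$dsm_noise_scale,
                        mosaic_error_sd = config$mosaic_error_sd,
                        surface_factor = sf,
                        seed = derive_seed(seed, 5000 + cmp))
    samples <- sample_soil_pixels(sim$dsm, sim$soil_mask,
                                  fraction = config$soil_fraction,
                                  seed = derive_seed(seed, 6000 + cmp))
    dtm <- interpolate_dtm(samples, sim$dsm, method = config$dtm_method,
                           stride = config$dtm_stride)
    hmap <- height_map(sim$dsm, dtm)
    polys <- plot_polygons_from_scene(scene)
    uas_ladders[[cmp]] <- cbind(campaign = cmp,
                                uas_plot_ladders(hmap, polys, step = 1))
    # --- Manual reference ---
    reference[[cmp]] <- generate_reference_heights(
      scene, n_replicates = config$reference_replicates,
      noise_sd = config$reference_noise_sd, campaign = cmp,
      seed = derive_seed(seed, 7000 + cmp))
  }
  ladders <- do.call(rbind, ladders)
  raw_ladders <- do.call(rbind, raw_ladders)
  uas_ladders <- do.call(rbind, uas_ladders)
  ultrasonic <- do.call(rbind, ultrasonic)
  reference <- do.call(rbind, reference)
  truth <- do.call(rbind, truth)
  report <- build_comparison_report(lidar_ladders = ladders,
                                    lidar_raw_ladders = raw_ladders,
                                    uas_ladders = uas_ladders,
                                    ultrasonic = ultrasonic, ref = reference)
  structure(list(ladders = ladders, raw_ladders = raw_ladders,
                 uas_ladders = uas_ladders, ultrasonic = ultrasonic,
                 reference = reference, truth = truth, report = report,
                 config = config, seed = seed),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("<simulation_study: %d campaigns x %d plots, seed=%d>\n",
              x$config$n_campaigns, x$config$n_plots, x$seed))
  print(x$report)
  invisible(x)
}

#' Score sensors from on-disk estimate files
#'
#' The same computation path as the tail of [run_simulation_study()], minus
#' generation: reads per-sensor inputs from the declared plain-text formats
#' and assembles the comparison report. Missing sensor files degrade
#' gracefully (that sensor is simply absent from the report).
#'
#' @param lidar_ladders_csv,lidar_raw_ladders_csv ladders CSVs
#'   (plot_id, campaign, position, percentile, height), or `NULL`.
#' @param uas_ladders_csv UAS ladders CSV, or `NULL`.
#' @param ultrasonic_csv readings CSV (plot_id, campaign, voltage_V,
#'   sensor_height_m), or `NULL`.
#' @param reference_csv reference heights CSV (plot_id, campaign, method,
#'   height_m); required.
#' @param unit_scale see [ultrasonic_height()].
#' @return a `comparison_report`.
#' @export
run_sensor_comparison <- function(lidar_ladders_csv = NULL,
                                  lidar_raw_ladders_csv = NULL,
                                  uas_ladders_csv = NULL,
                                  ultrasonic_csv = NULL,
                                  reference_csv, unit_scale = 0.01) {
  read_maybe <- function(path) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      warning("input not found, sensor skipped: ", path, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(path)
  }
  ref <- utils::read.csv(reference_csv)
  req <- c("plot_id", "campaign", "height_m")
  if (!all(req %in% names(ref))) {
    stop("parse error in ", reference_csv,
         ": needs columns plot_id, campaign, height_m", call. = FALSE)
  }
  us <- read_maybe(ultrasonic_csv)
  if (!is.null(us)) {
    us <- ultrasonic_heights_table(us, unit_scale = unit_scale)
    us <- data.frame(plot_id = us$plot_id, campaign = us$campaign,
                     height_m = us$height_m)
  }
  build_comparison_report(lidar_ladders = read_maybe(lidar_ladders_csv),
                          lidar_raw_ladders = read_maybe(lidar_raw_ladders_csv),
                          uas_ladders = read_maybe(uas_ladders_csv),
                          ultrasonic = us, ref = ref)
}
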