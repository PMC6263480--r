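# Shared fixture constructors. All fixtures are generated in code under
# fixed seeds; nothing is read from disk unless a test writes it first.

# One-scan scene: three plots in a row. Equal heights unless given, because
# the tilt-correction's working assumption (canopy tops parallel the
# ground) only holds when adjacent plots have similar heights.
triplet_scene <- function(heights = rep(0.8, 3), seed = 7,
                          slope_x = 0, slope_y = 0, roughness = 0.01) {
  generate_field_scene(
    scene_config(n_plots = 3, plots_per_row = 3, true_height = heights,
                 terrain = list(slope_x = slope_x, slope_y = slope_y,
                                roughness_sd = roughness)),
    seed = seed)
}

# Noise-free flat scene: every stochastic error source switched off, so
# generated heights are exactly recoverable through the pipeline.
noisefree_scene <- function(heights, seed = 1) {
  generate_field_scene(
    scene_config(n_plots = length(heights), plots_per_row = length(heights),
                 true_height = heights,
                 terrain = list(slope_x = 0, slope_y = 0, roughness_sd = 0)),
    seed = seed)
}

# A trim window wide enough that no simulated point is clipped: the scan
# covers exactly the three target plots, so the cloud carries no
# out-of-range points and the window is not binding for pose-recovery
# analysis (the standard window, applied in a tilted frame, clips edge
# points selectively by height).
trim_nonbinding <- function(cloud) trim_cloud(cloud, plot_width = 4)

# Uniform random mini point clouds for partition/oracle loops.
random_cloud <- function(n = 100, seed = 1) {
  canopyscan:::with_seed(seed, {
    point_cloud(cbind(x = stats::runif(n, -3, 3),
                      y = stats::runif(n, -2, 2),
                      z = stats::rnorm(n)))
  })
}

expect_cloud_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unclass(a), unclass(b), tolerance = tol,
               ignore_attr = TRUE)
}
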