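# Tilt correction and ground-baseline removal for cart-frame point clouds.
#
# The cart carrying the sensor bar rolls and pitches on uneven ground, so a
# raw cloud shows the terrain (and the canopy surface that parallels it)
# tilted in the sensor frame. The correction fits ordinary least-squares
# lines to the three coordinate-plane projections of the cloud, converts the
# slopes to angles, and counter-rotates until all three refit slopes vanish.
# Height above ground is then obtained by subtracting an estimated ground
# level (histogram-peak of the lower Z values by default, or the measured
# sensor height).

#' Ordinary least-squares slope of a coordinate-plane projection
#'
#' Regresses the second named coordinate on the first: `yz` fits z on y,
#' `xz` fits z on x, `xy` fits y on x.
#'
#' @param cloud a `point_cloud` (or n x 3 matrix).
#' @param projection one of `"yz"`, `"xz"`, `"xy"`.
#' @return named numeric vector `c(slope, intercept)`.
#' @export
fit_projection_slope <- function(cloud, projection = c("yz", "xz", "xy")) {
  projection <- match.arg(projection)
  ax <- switch(projection, yz = c(2L, 3L), xz = c(1L, 3L), xy = c(1L, 2L))
  nm <- c("x", "y", "z")
  a <- cloud[, ax[1]]
  b <- cloud[, ax[2]]
  if (length(a) < 2L) stop("fit error: need at least 2 points", call. = FALSE)
  va <- stats::var(a)
  if (!is.finite(va) || va <= 0) {
    stop("fit error: degenerate abscissae (no spread in ", nm[ax[1]], ")", call. = FALSE)
  }
  slope <- stats::cov(a, b) / va
  c(slope = slope, intercept = mean(b) - slope * mean(a))
}

#' Convert a fitted slope to an angle in degrees
#' @param slope unitless slope.
#' @return `atan(slope)` in degrees.
#' @export
slope_to_angle <- function(slope) {
  if (any(!is.finite(slope))) stop("slope must be finite", call. = FALSE)
  rad2deg(atan(slope))
}

#' Rotate a cloud about a coordinate axis through the origin
#'
#' Right-handed rotation about the named axis through the cloud origin (the
#' sensor optical center), preserving lengths; the origin is deliberately not
#' the centroid so sensor-height semantics survive rotation.
#'
#' @param cloud a `point_cloud`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle rotation angle in degrees.
#' @return the rotated `point_cloud` (frame state unchanged).
#' @export
rotate_cloud <- function(cloud, axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  if (!is.finite(angle)) stop("angle must be finite", call. = FALSE)
  R <- switch(axis, x = rot_x(angle), y = rot_y(angle), z = rot_z(angle))
  cloud_like(t(R %*% t(unclass(cloud))), cloud)
}

#' Cancel cart tilt by iterated projection fits and counter-rotations
#'
#' One pass fits the X-Y, X-Z and Y-Z projections in turn, each time
#' rotating the cloud about the orthogonal axis by the negated fitted angle
#' (xy about Z, xz about Y, yz about X). Because rotations about different
#' axes do not commute, passes repeat until all three refit slopes fall
#' below `tolerance`. The recovered roll/pitch/yaw are reported by Euler
#' decomposition (Rz.Ry.Rx convention) of the inverse of the accumulated
#' correction, i.e. the pose the correction undid.
#'
#' @param cloud a trimmed `point_cloud` with at least 3 non-collinear points.
#' @param tolerance slope tolerance for convergence (unitless, default 1e-6).
#' @param max_iterations maximum number of fit-and-rotate passes.
#' @return list with `cloud` (`frame_state = "corrected"`) and `estimate`, a
#'   `tilt_estimate` list: `theta_xy`, `theta_xz`, `theta_yz` (cumulative
#'   per-plane correction angles, degrees), `recovered_pose` (roll, pitch,
#'   yaw in degrees), `iterations`, `residual_slopes`, `converged`.
#' @export
correct_tilt <- function(cloud, tolerance = 1e-6, max_iterations = 10L) {
  if (frame_state(cloud) == "raw") {
    stop("correct_tilt expects a trimmed cloud", call. = FALSE)
  }
  if (nrow(cloud) < 3L) stop("need at least 3 points", call. = FALSE)
  work <- unclass(cloud)
  C <- diag(3)  # accumulated correction rotation
  cum <- c(xy = 0, xz = 0, yz = 0)
  it <- 0L
  converged <- FALSE
  planes <- list(c("xy", "z"), c("xz", "y"), c("yz", "x"))
  residual <- c(xy = NA_real_, xz = NA_real_, yz = NA_real_)
  while (it < max_iterations) {
    it <- it + 1L
    for (pl in planes) {
      proj <- pl[1]; axis <- pl[2]
      sl <- fit_projection_slope(work, proj)[["slope"]]
      ang <- slope_to_angle(sl)
      # a right-handed +rotation about Y tilts the x-axis toward -Z, so the
      # xz slope is cancelled by +angle, while xy and yz need -angle
      R <- switch(axis, x = rot_x(-ang), y = rot_y(ang), z = rot_z(-ang))
      work <- t(R %*% t(work))
      C <- R %*% C
      cum[proj] <- cum[proj] + ang
    }
    residual <- c(xy = fit_projection_slope(work, "xy")[["slope"]],
                  xz = fit_projection_slope(work, "xz")[["slope"]],
                  yz = fit_projection_slope(work, "yz")[["slope"]])
    if (all(abs(residual) < tolerance)) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("correct_tilt did not reach slope tolerance within max_iterations",
            call. = FALSE)
  }
  estimate <- structure(list(
    theta_xy = unname(cum["xy"]),
    theta_xz = unname(cum["xz"]),
    theta_yz = unname(cum["yz"]),
    recovered_pose = euler_zyx(solve(C)),
    iterations = it,
    residual_slopes = residual,
    converged = converged), class = "tilt_estimate")
  list(cloud = cloud_like(work, cloud, frame_state = "corrected"),
       estimate = estimate)
}

#' @export
print.tilt_estimate <- function(x, ...) {
  cat(sprintf(paste0("<tilt_estimate: recovered roll %.3f deg, pitch %.3f deg,",
                     " yaw %.3f deg; %d iteration(s), converged=%s>\n"),
              x$recovered_pose["roll"], x$recovered_pose["pitch"],
              x$recovered_pose["yaw"], x$iterations, x$converged))
  invisible(x)
}

#' Re-express Z as height above ground
#'
#' Estimates the ground level of a tilt-corrected cloud and subtracts it
#' from every Z, so ground points cluster at 0 and Z percentiles read as
#' canopy heights.
#'
#' Strategies:
#' \describe{
#'   \item{histogram_peak}{ground level = mean Z inside the maximal-count
#'     0.01 m bin of a histogram over the cloud's lower half-range (ground
#'     returns dominate the low-Z mode). Falls back to `sensor_height` with a
#'     warning when fewer than 50 points lie below the median.}
#'   \item{sensor_height}{ground level = `-sensor_height` (the measured
#'     sensor-to-soil distance).}
#'   \item{fixed}{ground level supplied directly via `ground_z`.}
#' }
#'
#' @param cloud a corrected `point_cloud`.
#' @param strategy `"histogram_peak"`, `"sensor_height"` or `"fixed"`.
#' @param sensor_height sensor height above soil, meters (required for
#'   `sensor_height`).
#' @param ground_z fixed ground level (required for `fixed`).
#' @param bin_width histogram bin width in meters (default 0.01).
#' @return list with `cloud` (`frame_state = "above_ground"`) and `baseline`
#'   (list: `ground_z`, `strategy`).
#' @export
correct_ground_baseline <- function(cloud,
                                    strategy = c("histogram_peak",
                                                 "sensor_height", "fixed"),
                                    sensor_height = NULL, ground_z = NULL,
                                    bin_width = 0.01) {
  strategy <- match.arg(strategy)
  if (!frame_state(cloud) %in% c("corrected", "above_ground")) {
    stop("correct_ground_baseline expects a tilt-corrected cloud", call. = FALSE)
  }
  z <- cloud[, "z"]
  if (strategy == "histogram_peak") {
    if (sum(z < stats::median(z)) < 50L) {
      if (is.null(sensor_height)) {
        stop("histogram baseline unsupported (<50 points below median) and no sensor_height fallback given",
             call. = FALSE)
      }
      warning("too few low points for a Z histogram; falling back to sensor_height baseline",
              call. = FALSE)
      strategy <- "sensor_height"
    }
  }
  gz <- switch(strategy,
    histogram_peak = {
      lo <- min(z)
      hi <- lo + (max(z) - lo) / 2
      zz <- z[z <= hi]
      # breaks anchored at the minimum; right-closed bins
      nb <- max(1L, ceiling((hi - lo) / bin_width))
      idx <- pmin(nb, pmax(1L, ceiling((zz - lo) / bin_width + 1e-12)))
      peak <- which.max(tabulate(idx, nbins = nb))
      mean(zz[idx == peak])
    },
    sensor_height = {
      if (is.null(sensor_height) || sensor_height <= 0) {
        stop("sensor_height strategy needs sensor_height > 0", call. = FALSE)
      }
      -sensor_height
    },
    fixed = {
      if (is.null(ground_z) || !is.finite(ground_z)) {
        stop("fixed strategy needs a finite ground_z", call. = FALSE)
      }
      ground_z
    })
  out <- unclass(cloud)
  out[, "z"] <- out[, "z"] - gz
  list(cloud = cloud_like(out, cloud, frame_state = "above_ground"),
       baseline = list(ground_z = gz, strategy = strategy))
}
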