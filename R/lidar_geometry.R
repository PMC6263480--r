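# Polar LiDAR record decoding and plot-frame windowing.
#
# The scanner considered here is a 16-channel spinning unit: channel
# elevation angles -15..+15 deg at 2 deg steps, azimuth in [0, 360),
# usable range up to 100 m. Records decode into a device Cartesian frame by
# the sensor's spherical convention (azimuth measured from +Y), then a rigid
# mounting transform places them in the cart frame.

LIDAR_CHANNELS <- seq(-15, 15, by = 2)

#' Decode polar LiDAR records into device-frame Cartesian coordinates
#'
#' Spherical-to-Cartesian conversion with the spinning-scanner convention:
#' `x = r cos(omega) sin(alpha)`, `y = r cos(omega) cos(alpha)`,
#' `z = r sin(omega)`, where omega is the channel elevation angle and alpha
#' the azimuth measured clockwise-from-+Y about the spin axis.
#'
#' @param records data.frame with columns `omega_deg` (one of the 16 channel
#'   angles), `azimuth_deg` in \[0, 360) and `range_m` in (0, 100\].
#' @return n x 3 matrix of device-frame coordinates (meters).
#' @export
decode_records <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("omega_deg", "azimuth_deg", "range_m")
  if (!all(req %in% names(records))) {
    stop("records need columns omega_deg, azimuth_deg, range_m", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  if (any(records$range_m <= 0 | records$range_m > 100)) {
    stop("invalid record: range_m must lie in (0, 100]", call. = FALSE)
  }
  if (any(!records$omega_deg %in% LIDAR_CHANNELS)) {
    stop("invalid record: omega_deg must be one of the 16 channel angles", call. = FALSE)
  }
  om <- deg2rad(records$omega_deg)
  az <- deg2rad(records$azimuth_deg)
  r <- records$range_m
  cbind(x = r * cos(om) * sin(az),
        y = r * cos(om) * cos(az),
        z = r * sin(om))
}

#' Default device-to-cart mounting transform
#'
#' Maps the device spin axis (+Z) onto the travel axis (+Y) so the azimuth
#' sweep fans across the plot axis X and downward: a rotation of -90 deg
#' about X with no translation. The on-axis ray (omega = 0, alpha = 0) then
#' points straight down at the crop.
#'
#' @return list with elements `rotation` (3 x 3) and `translation` (length 3).
#' @export
default_mount <- function() {
  list(rotation = rot_x(-90), translation = c(0, 0, 0))
}

#' Apply a rigid mounting transform to device-frame points
#'
#' @param points n x 3 device-frame matrix (from [decode_records()]).
#' @param mount list with `rotation` (proper orthogonal 3 x 3) and
#'   `translation` (length-3 numeric); defaults to [default_mount()].
#' @return a `point_cloud` in the cart frame (`frame_state = "raw"`).
#' @export
apply_mounting <- function(points, mount = default_mount()) {
  R <- mount$rotation
  t <- mount$translation
  if (is.null(R)) R <- diag(3)
  if (is.null(t)) t <- c(0, 0, 0)
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop("mount$rotation must be a proper rigid rotation (orthogonal, det +1)",
         call. = FALSE)
  }
  if (length(t) != 3L || !all(is.finite(t))) {
    stop("mount$translation must be a finite length-3 vector", call. = FALSE)
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  xyz <- t(R %*% t(points)) + rep(t, each = nrow(points))
  point_cloud(xyz, frame_state = "raw")
}

#' Window polar records by azimuth
#'
#' Keeps records with azimuth in the half-open window `[az_lo, az_hi)`,
#' preserving order; the half-open convention avoids double-counting the
#' window seam when complementary windows are combined.
#'
#' @param records data.frame of polar records (see [decode_records()]).
#' @param az_lo,az_hi window bounds in degrees, `az_lo < az_hi`.
#' @return the filtered records (possibly zero rows).
#' @export
filter_fov <- function(records, az_lo, az_hi) {
  if (!(az_lo < az_hi)) stop("az_lo must be < az_hi", call. = FALSE)
  records[records$azimuth_deg >= az_lo & records$azimuth_deg < az_hi, ,
          drop = FALSE]
}

#' Trim a cloud to the three-plot window in X
#'
#' Retains exactly the points with `|x| <= 1.5 * plot_width` (closed
#' interval), the across-plot window covering the middle plot and both side
#' plots of one static scan.
#'
#' @param cloud a `point_cloud`.
#' @param plot_width plot width in meters (center-to-center alleyway
#'   distance; 1.524 m in the motivating field layout).
#' @return the trimmed `point_cloud` (`frame_state = "trimmed"`).
#' @export
trim_cloud <- function(cloud, plot_width = 1.524) {
  if (plot_width <= 0) stop("plot_width must be > 0", call. = FALSE)
  keep <- abs(cloud[, "x"]) <= 1.5 * plot_width
  cloud_like(unclass(cloud)[keep, , drop = FALSE], cloud, frame_state = "trimmed")
}

#' Split a trimmed cloud into left / middle / right plot clouds
#'
#' Partitions by X against the two borders at `+/- 0.5 * plot_width`; border
#' points go to the middle plot. Every input point lands in exactly one part.
#'
#' @param cloud a trimmed `point_cloud` (later states allowed).
#' @param plot_width plot width in meters.
#' @return named list of `point_cloud`s: `left`, `middle`, `right`; each
#'   carries a `position` attribute (`"side"` or `"middle"`).
#' @export
split_cloud <- function(cloud, plot_width = 1.524) {
  if (frame_state(cloud) == "raw") {
    stop("split_cloud requires a trimmed cloud (call trim_cloud first)", call. = FALSE)
  }
  b <- 0.5 * plot_width
  x <- cloud[, "x"]
  parts <- list(
    left = unclass(cloud)[x < -b, , drop = FALSE],
    middle = unclass(cloud)[abs(x) <= b, , drop = FALSE],
    right = unclass(cloud)[x > b, , drop = FALSE])
  out <- lapply(parts, cloud_like, template = cloud)
  attr(out$left, "position") <- "side"
  attr(out$middle, "position") <- "middle"
  attr(out$right, "position") <- "side"
  out
}

#' Read polar LiDAR records from CSV
#' @param path CSV with header `omega_deg, azimuth_deg, range_m`.
#' @return data.frame of records.
#' @export
read_lidar_records <- function(path) {
  df <- utils::read.csv(path)
  req <- c("omega_deg", "azimuth_deg", "range_m")
  if (!all(req %in% names(df))) {
    stop("record CSV must have columns omega_deg, azimuth_deg, range_m: ",
         path, call. = FALSE)
  }
  df
}
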