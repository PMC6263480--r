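# Candidate plant-height extraction: percentile ladders from plot clouds
# and height-map pixels, and ultrasonic voltage-to-height conversion.

#' Calibration coefficients of the ultrasonic rangefinder
#'
#' Lab-calibrated linear voltage-to-distance conversion
#' `D = slope * V + intercept` with the as-printed coefficients
#' slope = 29.116 and intercept = 11.641 (distance units per volt and
#' distance units). Taken at face value these are dimensionally inconsistent
#' with meters over a 0-10 V, 4.27 m-range sensor; see
#' [ultrasonic_height()]'s `unit_scale` for the two supported readings.
#'
#' @param slope distance units per volt (> 0).
#' @param intercept distance units.
#' @return list with `slope` and `intercept`.
#' @export
calibration_coefficients <- function(slope = 29.116, intercept = 11.641) {
  if (slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  list(slope = slope, intercept = intercept)
}

#' Convert an ultrasonic voltage to a distance
#'
#' `D = slope * V + intercept` in the calibration's native distance unit.
#'
#' @param V voltage(s) in \[0, 10\] volts.
#' @param coeffs [calibration_coefficients()].
#' @return distance(s) in calibration units.
#' @export
ultrasonic_distance <- function(V, coeffs = calibration_coefficients()) {
  if (any(V < 0 | V > 10)) {
    stop("range error: voltage must lie in [0, 10] V", call. = FALSE)
  }
  coeffs$slope * V + coeffs$intercept
}

#' Ultrasonic canopy height from sensor height and echo distance
#'
#' `H_c = H_s - D * unit_scale`. `unit_scale` converts the calibration's
#' native distance unit to meters: 0.01 (default) reads the calibration
#' output as centimeters — the dimensionally consistent interpretation for a
#' 0-10 V sensor ranging to 4.27 m — while 1 takes the printed
#' meters-in-meters-out form at face value. Negative heights are valid
#' observations (cart tilt can make the soil path longer than the measured
#' sensor height) and are flagged, not clamped.
#'
#' @param sensor_height sensor height above soil, meters (> 0).
#' @param D distance(s) in calibration units (from [ultrasonic_distance()]).
#' @param unit_scale meters per calibration unit (> 0; default 0.01).
#' @return canopy height(s) in meters, with attribute `negative` (logical
#'   vector flagging below-ground readings).
#' @export
ultrasonic_height <- function(sensor_height, D, unit_scale = 0.01) {
  if (sensor_height <= 0) stop("sensor_height must be > 0", call. = FALSE)
  if (unit_scale <= 0) stop("unit_scale must be > 0", call. = FALSE)
  hc <- sensor_height - D * unit_scale
  attr(hc, "negative") <- hc < 0
  hc
}

#' Cumulative percentile ladder of a height set
#'
#' Heights at the percentile grid `step, 2*step, ..., 100` (the 0% endpoint
#' is excluded, so 0.5% steps give exactly 200 entries and 1% steps exactly
#' 100), each computed by linear interpolation between adjacent order
#' statistics. The ladder is the candidate set from which the optimal
#' height estimator percentile is chosen.
#'
#' @param values non-empty numeric vector of heights (meters).
#' @param step percentile step in percent; must divide 100 into a whole
#'   number of entries (0.5 for LiDAR plot clouds, 1 for height-map pixels).
#' @param source label: `"lidar"` or `"uas"` (informational).
#' @param plot_id optional plot identifier attached to the ladder.
#' @return data.frame with columns `percentile` (strictly increasing) and
#'   `height` (non-decreasing), plus attributes `source` and `plot_id`.
#' @export
percentile_ladder <- function(values, step = 0.5, source = "lidar",
                              plot_id = NA) {
  if (length(values) == 0L || all(is.na(values))) {
    stop("percentile_ladder: empty height set", call. = FALSE)
  }
  n_entries <- 100 / step
  if (abs(n_entries - round(n_entries)) > 1e-9) {
    stop("step must divide 100 into a whole number of entries", call. = FALSE)
  }
  grid <- seq_len(round(n_entries)) * step
  out <- data.frame(percentile = grid,
                    height = height_at_percentile(values, grid))
  attr(out, "source") <- source
  attr(out, "plot_id") <- plot_id
  out
}

#' Write percentile ladders as CSV
#' @param ladders data.frame with columns plot_id, campaign (optional),
#'   position (optional), percentile, height.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ladders_csv <- function(ladders, path) {
  utils::write.csv(ladders, path, row.names = FALSE)
  invisible(path)
}

#' Read percentile ladders from CSV
#' @param path CSV path written by [write_ladders_csv()].
#' @return data.frame of ladders.
#' @export
read_ladders_csv <- function(path) utils::read.csv(path)

#' Convert ultrasonic readings to canopy heights, tabular form
#'
#' Applies [ultrasonic_distance()] and [ultrasonic_height()] to a readings
#' table, the batch form used by the study pipeline.
#'
#' @param readings data.frame with columns `plot_id`, `voltage_V`,
#'   `sensor_height_m` (and optionally `campaign`).
#' @param coeffs [calibration_coefficients()].
#' @param unit_scale see [ultrasonic_height()].
#' @return the readings with `distance` (calibration units), `height_m` and
#'   `negative` columns appended.
#' @export
ultrasonic_heights_table <- function(readings,
                                     coeffs = calibration_coefficients(),
                                     unit_scale = 0.01) {
  req <- c("plot_id", "voltage_V", "sensor_height_m")
  if (!all(req %in% names(readings))) {
    stop("readings need columns plot_id, voltage_V, sensor_height_m", call. = FALSE)
  }
  d <- ultrasonic_distance(readings$voltage_V, coeffs)
  out <- readings
  out$distance <- d
  out$height_m <- readings$sensor_height_m - d * unit_scale
  out$negative <- out$height_m < 0
  out
}
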