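# Internal numerical helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators in the package route their randomness through this helper so
#' that every simulated object is a pure function of (config, seed) and
#' calling a generator never perturbs the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("configuration error: 'seed' must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

#' Truncated normal sampler (inverse-CDF)
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n` in `[lower, upper]`.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm((lower - mean) / sd)
  phi <- stats::pnorm((upper - mean) / sd)
  u <- stats::runif(n, plo, phi)
  mean + sd * stats::qnorm(u)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Matches the round-half-up convention used for the printed derived
#' statistics (2 decimals for percentages, 4 for meters), unlike base
#' `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.002575, 4)  # 0.0026
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Degrees <-> radians
deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Right-handed rotation matrices about the coordinate axes (column-vector
# convention: p' = R %*% p).
rot_x <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,
           0, c, -s,
           0, s, c), 3, 3, byrow = TRUE)
}
rot_y <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s,
           0, 1, 0,
           -s, 0, c), 3, 3, byrow = TRUE)
}
rot_z <- function(angle_deg) {
  a <- deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0,
           s, c, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Euler decomposition of M = Rz(yaw) %*% Ry(pitch) %*% Rx(roll),
# returning angles in degrees. Valid away from the pitch = +/-90 deg
# singularity, far outside the +/-30 deg poses simulated here.
euler_zyx <- function(M) {
  pitch <- -asin(max(-1, min(1, M[3, 1])))
  roll <- atan2(M[3, 2], M[3, 3])
  yaw <- atan2(M[2, 1], M[1, 1])
  c(roll = rad2deg(roll), pitch = rad2deg(pitch), yaw = rad2deg(yaw))
}

#' Height at a cumulative percentile (linear interpolation)
#'
#' Thin wrapper over the type-7 quantile (linear interpolation between
#' adjacent order statistics), the convention used for every percentile in
#' the package so ladders, ground-truth records and oracles agree.
#'
#' @param values numeric vector of heights.
#' @param percent percentile level(s) in (0, 100].
#' @return interpolated height(s) in the units of `values`.
#' @export
height_at_percentile <- function(values, percent) {
  if (length(values) == 0L) stop("empty height set", call. = FALSE)
  stats::quantile(values, probs = percent / 100, type = 7, names = FALSE)
}

#' Percentile of a height within a set (inverse of `height_at_percentile`)
#'
#' Returns the continuous percentile p such that the linearly interpolated
#' p-th percentile of `values` equals `height`. Used by the synthetic scene
#' generator to record, for each plot, the percentile at which the true
#' height sits in the generated above-ground height set.
#'
#' @param values numeric vector of heights.
#' @param height height whose percentile is sought; must lie within
#'   `range(values)`.
#' @return percentile in \[0, 100\].
#' @export
percentile_of_height <- function(values, height) {
  s <- sort(values)
  n <- length(s)
  if (n == 0L) stop("empty height set", call. = FALSE)
  if (height < s[1] || height > s[n]) {
    stop("height lies outside the range of the value set", call. = FALSE)
  }
  if (n == 1L) return(100)
  k <- max(which(s <= height))
  if (k == n) return(100)
  frac <- if (s[k + 1] > s[k]) (height - s[k]) / (s[k + 1] - s[k]) else 0
  100 * (k - 1 + frac) / (n - 1)
}
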