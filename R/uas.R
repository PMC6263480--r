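# UAS plant-height map construction: soil-pixel sampling, DTM interpolation
# by ordinary kriging (or inverse-distance weighting), and DSM - DTM
# subtraction.

#' Randomly sample soil pixels from a DSM
#'
#' Uniform random subset, without replacement, of the cells marked as soil;
#' deterministic under the seed. These samples anchor the terrain-model
#' interpolation.
#'
#' @param dsm a `height_raster` (role dsm).
#' @param soil_mask a congruent `height_raster` with 1 at soil cells.
#' @param fraction fraction of soil cells to sample, in (0, 1\] (default
#'   0.4, i.e. roughly 40% of all soil pixels).
#' @param seed integer seed.
#' @return a `soil_sample` list: `row`, `col` (cell indices), `x`, `y`
#'   (cell-center coordinates, meters), `z` (sampled elevations),
#'   `sampling_fraction`, `seed`.
#' @export
sample_soil_pixels <- function(dsm, soil_mask, fraction = 0.4, seed = 1) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!rasters_congruent(dsm, soil_mask)) {
    stop("congruence error: dsm and soil_mask grids differ", call. = FALSE)
  }
  idx <- which(soil_mask$values == 1)
  if (!length(idx)) stop("zero soil cells in the mask", call. = FALSE)
  n <- max(1L, round(fraction * length(idx)))
  take <- with_seed(seed, sample(idx, n))
  nr <- nrow(dsm$values)
  row <- (take - 1L) %% nr + 1L
  col <- (take - 1L) %/% nr + 1L
  cc <- cell_centers(dsm)
  structure(list(row = row, col = col,
                 x = cc$x[col], y = cc$y[row],
                 z = dsm$values[take],
                 sampling_fraction = fraction, seed = seed),
            class = "soil_sample")
}

#' @export
print.soil_sample <- function(x, ...) {
  cat(sprintf("<soil_sample: %d cells (fraction %.2f), elevation %.3f-%.3f m>\n",
              length(x$z), x$sampling_fraction, min(x$z), max(x$z)))
  invisible(x)
}

# Exponential variogram model gamma(h) = nugget + psill * (1 - exp(-h/range)).
exp_variogram <- function(h, pars) {
  pars[1] + pars[2] * (1 - exp(-h / pars[3]))
}

# Fit the exponential model to the empirical semivariance by least squares.
# Returns c(nugget, psill, range); nugget floored at 1e-6 so the kriging
# matrix stays well conditioned while sample cells are still honored.
fit_exponential_variogram <- function(x, y, z, n_bins = 15) {
  n <- length(z)
  d <- as.matrix(stats::dist(cbind(x, y)))
  g <- 0.5 * outer(z, z, "-")^2
  ut <- upper.tri(d)
  dv <- d[ut]; gv <- g[ut]
  maxd <- max(dv) / 2
  keep <- dv > 0 & dv <= maxd
  dv <- dv[keep]; gv <- gv[keep]
  bins <- cut(dv, breaks = seq(0, maxd, length.out = n_bins + 1),
              include.lowest = TRUE)
  bd <- tapply(dv, bins, mean)
  bg <- tapply(gv, bins, mean)
  ok <- is.finite(bd) & is.finite(bg)
  bd <- bd[ok]; bg <- bg[ok]
  sill0 <- max(stats::var(z), 1e-12)
  start <- c(nugget = 1e-6, psill = sill0, range = maxd / 3)
  if (length(bd) >= 3) {
    obj <- function(p) {
      p <- pmax(p, c(1e-6, 1e-12, 1e-6))
      sum((exp_variogram(bd, p) - bg)^2)
    }
    fit <- try(stats::optim(start, obj, method = "Nelder-Mead",
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      start <- pmax(fit$par, c(1e-6, 1e-12, 1e-6))
    }
  }
  unname(start)
}

# Solve the ordinary-kriging system for prediction locations (px, py) from
# samples (x, y, z). The semivariance matrix has zeros on the diagonal, so
# the predictor honors the data exactly at sample locations. Because the
# predictor is linear in the right-hand side, the per-cell weight solve
# collapses into one fixed vector w = t(inv(A)[1:n, ]) z, and prediction is
# a single matrix-vector product per chunk of cells.
krige_predict <- function(x, y, z, pars, px, py, chunk = 20000L) {
  n <- length(z)
  d <- as.matrix(stats::dist(cbind(x, y)))
  G <- exp_variogram(d, pars)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  w <- solve(t(A), c(z, 0))  # w_i = sum_j inv(A)[j, i] zt_j with zt = (z, 0)
  s2 <- x^2 + y^2
  out <- numeric(length(px))
  for (s in seq(1, length(px), by = chunk)) {
    e <- min(s + chunk - 1L, length(px))
    m <- e - s + 1L
    D2 <- -2 * tcrossprod(cbind(x, y), cbind(px[s:e], py[s:e])) + s2 +
      rep(px[s:e]^2 + py[s:e]^2, each = n)
    D0 <- sqrt(pmax(D2, 0))
    g0 <- exp_variogram(D0, pars)
    # snap coincident locations (sub-micrometer in field units; the expanded
    # distance form carries ~1e-13 m^2 of cancellation error)
    g0[D0 < 1e-6] <- 0
    out[s:e] <- as.vector(crossprod(g0, w[seq_len(n)])) + w[n + 1L]
  }
  out
}

#' Interpolate a DTM from sampled soil pixels
#'
#' Fills the full raster grid from the soil samples. The default method is
#' ordinary kriging with an exponential variogram fitted to the empirical
#' semivariance by least squares (nugget floored at 1e-6); inverse-distance
#' weighting (power 2) is available as a fallback and is used automatically
#' when the kriging system is degenerate (e.g. collinear samples). Both
#' interpolators honor the sampled elevations exactly at sample cells.
#'
#' For tractability the kriging system uses at most `max_points` samples
#' (deterministic even thinning when more are supplied); predictions are
#' chunked so memory stays bounded. With `stride > 1` the surface is
#' evaluated on a strided sub-lattice and bilinearly resampled to the full
#' grid (the terrain model is smooth by construction, so the resampling
#' error is negligible), and the sampled cells are set to their exact
#' elevations so the interpolating property is preserved.
#'
#' @param samples a `soil_sample` (>= 4 points spanning both dimensions for
#'   kriging).
#' @param template a `height_raster` defining the output grid.
#' @param method `"kriging"` (default) or `"idw"`.
#' @param max_points cap on the number of samples in the kriging system.
#' @param stride prediction-lattice stride in cells (default 1 = evaluate
#'   every cell).
#' @return a `height_raster` with role `"dtm"`.
#' @export
interpolate_dtm <- function(samples, template, method = c("kriging", "idw"),
                            max_points = 500L, stride = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(samples, "soil_sample"))
  n <- length(samples$z)
  if (n < 4) stop("need at least 4 soil samples", call. = FALSE)
  x <- samples$x; y <- samples$y; z <- samples$z
  if (n > max_points) {
    keep <- unique(round(seq(1, n, length.out = max_points)))
    x <- x[keep]; y <- y[keep]; z <- z[keep]
  }
  cc <- cell_centers(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  stride <- max(1L, as.integer(stride))
  ri <- if (stride > 1L) unique(c(seq(1L, nr, by = stride), nr)) else seq_len(nr)
  ci <- if (stride > 1L) unique(c(seq(1L, nc, by = stride), nc)) else seq_len(nc)
  px <- rep(cc$x[ci], each = length(ri))
  py <- rep(cc$y[ri], times = length(ci))
  vals <- NULL
  if (method == "kriging") {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      warning("soil samples are collinear in grid position; falling back to IDW",
              call. = FALSE)
      method <- "idw"
    } else {
      pars <- fit_exponential_variogram(x, y, z)
      vals <- try(krige_predict(x, y, z, pars, px, py), silent = TRUE)
      if (inherits(vals, "try-error")) {
        warning("kriging system is singular; falling back to IDW", call. = FALSE)
        method <- "idw"
        vals <- NULL
      }
    }
  }
  if (is.null(vals)) vals <- idw_predict(x, y, z, px, py, power = 2)
  sub <- matrix(vals, length(ri), length(ci))
  full <- if (stride > 1L) bilinear_expand(sub, ri, ci, nr, nc) else sub
  if (stride > 1L) {
    # honor the data exactly at sampled cells (kriging's own property,
    # enforced explicitly on the resampled lattice)
    full[cbind(samples$row, samples$col)] <- samples$z
  }
  out <- height_raster(full, origin = template$origin,
                       cell_size = template$cell_size,
                       nodata = template$nodata, role = "dtm")
  attr(out, "method") <- method
  out
}

# Bilinear interpolation of a sub-lattice (given at rows ri, cols ci of an
# nr x nc grid) to the full grid.
bilinear_expand <- function(sub, ri, ci, nr, nc) {
  rf <- stats::approx(ri, seq_along(ri), xout = seq_len(nr))$y
  cf <- stats::approx(ci, seq_along(ci), xout = seq_len(nc))$y
  r0 <- pmin(floor(rf), nrow(sub) - 1L); wr <- rf - r0
  c0 <- pmin(floor(cf), ncol(sub) - 1L); wc <- cf - c0
  a <- sub[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- sub[cbind(rep(r0, nc), rep(c0 + 1L, each = nr))]
  d <- sub[cbind(rep(r0 + 1L, nc), rep(c0, each = nr))]
  e <- sub[cbind(rep(r0 + 1L, nc), rep(c0 + 1L, each = nr))]
  wrv <- rep(wr, nc); wcv <- rep(wc, each = nr)
  matrix((1 - wrv) * (1 - wcv) * a + (1 - wrv) * wcv * b +
           wrv * (1 - wcv) * d + wrv * wcv * e, nr, nc)
}

# Inverse-distance weighting, exact at sample locations.
idw_predict <- function(x, y, z, px, py, power = 2, chunk = 20000L) {
  out <- numeric(length(px))
  for (s in seq(1, length(px), by = chunk)) {
    e <- min(s + chunk - 1L, length(px))
    dx <- outer(x, px[s:e], "-")
    dy <- outer(y, py[s:e], "-")
    D <- sqrt(dx^2 + dy^2)
    hit <- apply(D, 2, function(col) { i <- which(col == 0); if (length(i)) i[1] else NA_integer_ })
    W <- 1 / pmax(D, 1e-12)^power
    pred <- as.vector(crossprod(W, z)) / colSums(W)
    exact <- !is.na(hit)
    pred[exact] <- z[hit[exact]]
    out[s:e] <- pred
  }
  out
}

#' Plant height map: DSM minus DTM
#'
#' Cellwise subtraction of congruent grids. Nodata propagates; negative
#' heights are preserved (summarized in the `negative_cells` attribute), as
#' percentile selection downstream is robust to a negative tail.
#'
#' @param dsm,dtm congruent `height_raster`s.
#' @return a `height_raster` with role `"height_map"`.
#' @export
height_map <- function(dsm, dtm) {
  if (!rasters_congruent(dsm, dtm)) {
    stop("congruence error: DSM and DTM grids differ in shape, origin or cell size",
         call. = FALSE)
  }
  v <- dsm$values - dtm$values
  v[dsm$values == dsm$nodata | dtm$values == dtm$nodata] <- NA
  out <- height_raster(v, origin = dsm$origin, cell_size = dsm$cell_size,
                       nodata = dsm$nodata, role = "height_map")
  attr(out, "negative_cells") <- sum(v < 0, na.rm = TRUE)
  out
}

#' Per-plot pixel percentile ladders from a height map
#'
#' Extracts each plot's pixel values by the cell-center zonal rule and
#' builds a 1%-step percentile ladder (100 entries) per plot.
#'
#' @param hmap a `height_raster` (role height_map).
#' @param polygons list of plot polygons.
#' @param step percentile step, percent (default 1).
#' @return data.frame with columns plot_id, percentile, height.
#' @export
uas_plot_ladders <- function(hmap, polygons, step = 1) {
  out <- lapply(polygons, function(p) {
    vals <- plot_pixel_values(hmap, p)
    lad <- percentile_ladder(vals, step = step, source = "uas",
                             plot_id = p$plot_id)
    cbind(plot_id = p$plot_id, lad)
  })
  do.call(rbind, out)
}
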