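# Minimal single-band raster container, ESRI ASCII grid I/O, GeoJSON plot
# polygons, and zonal pixel extraction.

#' Construct a single-band raster
#'
#' Values are stored as a matrix whose first row is the top (northernmost)
#' row of cells; `origin` is the x/y of the upper-left cell corner and
#' `cell_size` the ground sampling distance, both in meters.
#'
#' @param values numeric matrix (rows top to bottom).
#' @param origin length-2 numeric, upper-left corner (x, y).
#' @param cell_size cell edge length, meters (> 0).
#' @param nodata nodata marker (default -9999).
#' @param role one of `"dsm"`, `"dtm"`, `"height_map"`, `"soil_mask"`,
#'   `"generic"`.
#' @return a `height_raster` object.
#' @export
height_raster <- function(values, origin = c(0, 0), cell_size = 1,
                          nodata = -9999, role = "generic") {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  role <- match.arg(role, c("dsm", "dtm", "height_map", "soil_mask", "generic"))
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = cell_size, nodata = nodata, role = role),
            class = "height_raster")
}

#' @export
print.height_raster <- function(x, ...) {
  cat(sprintf("<height_raster [%s]: %d x %d cells, cell_size=%g m, origin=(%g, %g)>\n",
              x$role, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell-center coordinates of a raster
#' @param raster a `height_raster`.
#' @return list with numeric vectors `x` (by column) and `y` (by row, top
#'   row first).
#' @export
cell_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  list(x = raster$origin[1] + (seq_len(nc) - 0.5) * raster$cell_size,
       y = raster$origin[2] - (seq_len(nr) - 0.5) * raster$cell_size)
}

# TRUE when two rasters share shape, origin and cell size.
rasters_congruent <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$origin - b$origin)) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Write a raster as an ESRI ASCII grid (.asc)
#'
#' Plain-text single-band raster interchangeable with standard GIS tools.
#'
#' @param raster a `height_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- raster$origin[2] - nr * raster$cell_size
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", raster$cell_size),
           sprintf("NODATA_value %g", raster$nodata))
  v[is.na(v)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#' @param path .asc file path.
#' @param role raster role to stamp (see [height_raster()]).
#' @return a `height_raster`; nodata cells become `NA`.
#' @export
read_asc <- function(path, role = "generic") {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[(i + 1):length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == nodata] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  height_raster(v, origin = origin, cell_size = hdr$cellsize,
                nodata = nodata, role = role)
}

#' Build a rectangular plot polygon
#' @param xmin,ymin,xmax,ymax rectangle bounds, meters.
#' @param plot_id plot identifier.
#' @return list with `plot_id` and `coords` (closed ring, n x 2 matrix).
#' @export
plot_polygon <- function(xmin, ymin, xmax, ymax, plot_id) {
  list(plot_id = plot_id,
       coords = cbind(x = c(xmin, xmax, xmax, xmin, xmin),
                      y = c(ymin, ymin, ymax, ymax, ymin)))
}

#' Write plot delineation polygons as GeoJSON
#' @param polygons list of polygons from [plot_polygon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plot_geojson <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    ring <- lapply(seq_len(nrow(p$coords)), function(i) unname(p$coords[i, ]))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot delineation polygons from GeoJSON
#' @param path GeoJSON FeatureCollection of Polygons with a `plot_id`
#'   property.
#' @return list of polygons (as from [plot_polygon()]).
#' @export
read_plot_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  lapply(g$features, function(f) {
    if (f$geometry$type != "Polygon") {
      stop("only Polygon features are supported", call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(pt) c(x = pt[[1]], y = pt[[2]])))
    list(plot_id = f$properties$plot_id, coords = coords)
  })
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
# Edges on the lower-left are counted inside by the half-open crossing rule.
points_in_polygon <- function(px, py, coords) {
  n <- nrow(coords) - 1L  # closed ring
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Pixel values of a raster inside a plot polygon
#'
#' Zonal extraction by the cell-center rule: returns the values of all
#' non-nodata cells whose center falls inside the polygon.
#'
#' @param raster a `height_raster`.
#' @param polygon a polygon (as from [plot_polygon()] /
#'   [read_plot_geojson()]).
#' @return numeric vector of cell values.
#' @export
plot_pixel_values <- function(raster, polygon) {
  cc <- cell_centers(raster)
  bx <- range(polygon$coords[, 1]); by <- range(polygon$coords[, 2])
  cols <- which(cc$x >= bx[1] - raster$cell_size & cc$x <= bx[2] + raster$cell_size)
  rows <- which(cc$y >= by[1] - raster$cell_size & cc$y <= by[2] + raster$cell_size)
  if (!length(cols) || !length(rows)) {
    stop("zero covered cells for plot ", polygon$plot_id,
         " (polygon outside raster extent)", call. = FALSE)
  }
  px <- rep(cc$x[cols], each = length(rows))
  py <- rep(cc$y[rows], times = length(cols))
  inside <- points_in_polygon(px, py, polygon$coords)
  sub <- raster$values[rows, cols, drop = FALSE]
  vals <- as.vector(sub)[inside]
  vals <- vals[!is.na(vals) & vals != raster$nodata]
  if (!length(vals)) {
    stop("zero covered cells for plot ", polygon$plot_id, call. = FALSE)
  }
  vals
}
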