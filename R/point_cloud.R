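# Point-cloud container and plain-format I/O.

FRAME_STATES <- c("raw", "trimmed", "corrected", "above_ground")

#' Construct a point cloud
#'
#' A point cloud is an n x 3 numeric matrix (columns x, y, z, meters) in the
#' cart frame — origin at the sensor optical center, X across plots toward
#' increasing plot index, Y along the travel direction, Z up — carrying a
#' `frame_state` that records how far through the processing chain the cloud
#' has moved. States advance only forward through
#' raw -> trimmed -> corrected -> above_ground.
#'
#' @param xyz numeric matrix or data.frame with columns x, y, z.
#' @param frame_state one of `"raw"`, `"trimmed"`, `"corrected"`,
#'   `"above_ground"`.
#' @return a `point_cloud` object.
#' @export
point_cloud <- function(xyz, frame_state = "raw") {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  xyz <- unname(as.matrix(xyz))
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("a point cloud needs exactly 3 columns (x, y, z)", call. = FALSE)
  if (nrow(xyz) > 0L && !all(is.finite(xyz))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  frame_state <- match.arg(frame_state, FRAME_STATES)
  colnames(xyz) <- c("x", "y", "z")
  structure(xyz, class = c("point_cloud", "matrix", "array"),
            frame_state = frame_state)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points, frame_state=%s>\n",
              nrow(x), frame_state(x)))
  invisible(x)
}

#' Frame state of a point cloud
#' @param cloud a `point_cloud`.
#' @return character scalar.
#' @export
frame_state <- function(cloud) attr(cloud, "frame_state")

# Advance a cloud's frame state; moving backwards is a programming error.
set_frame_state <- function(cloud, state) {
  state <- match.arg(state, FRAME_STATES)
  cur <- match(frame_state(cloud), FRAME_STATES)
  new <- match(state, FRAME_STATES)
  if (new < cur) {
    stop(sprintf("frame_state may only advance (have '%s', asked for '%s')",
                 frame_state(cloud), state), call. = FALSE)
  }
  attr(cloud, "frame_state") <- state
  cloud
}

# Rebuild a point_cloud from a coordinate matrix, keeping (or setting) state.
cloud_like <- function(xyz, template, frame_state = NULL) {
  pc <- point_cloud(xyz, frame_state = "raw")
  attr(pc, "frame_state") <- if (is.null(frame_state)) frame_state(template) else frame_state
  pc
}

#' Write a point cloud as ASCII PLY
#'
#' Plain-text PLY with double-precision x, y, z properties, readable by
#' standard point-cloud viewers.
#'
#' @param cloud a `point_cloud`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  n <- nrow(cloud)
  header <- c(
    "ply",
    "format ascii 1.0",
    "comment canopyscan point cloud",
    sprintf("comment frame_state %s", frame_state(cloud)),
    sprintf("element vertex %d", n),
    "property double x",
    "property double y",
    "property double z",
    "end_header")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0) {
    utils::write.table(format(unclass(cloud), digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Supports the subset written by [write_ply()]: ASCII format, a single
#' vertex element with x, y, z as its first three properties.
#'
#' @param path PLY file path.
#' @return a `point_cloud` (frame_state restored from the file comment when
#'   present, otherwise `"raw"`).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file (no end_header): ", path, call. = FALSE)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) {
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", header, value = TRUE)[1]))
  state_line <- grep("^comment frame_state ", header, value = TRUE)
  state <- if (length(state_line)) sub("^comment frame_state ", "", state_line[1]) else "raw"
  if (is.na(nv) || nv == 0L) return(point_cloud(matrix(numeric(0), ncol = 3), state))
  body <- lines[(end + 1):(end + nv)]
  xyz <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                               function(f) as.numeric(f[1:3])))
  point_cloud(xyz, frame_state = state)
}

#' Write a point cloud as CSV (header x,y,z)
#' @param cloud a `point_cloud`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  utils::write.csv(as.data.frame(unclass(cloud)), path, row.names = FALSE)
  invisible(path)
}

#' Read a point cloud from CSV (header x,y,z)
#' @param path CSV file path.
#' @param frame_state state to stamp on the cloud (CSV carries none).
#' @return a `point_cloud`.
#' @export
read_cloud_csv <- function(path, frame_state = "raw") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("cloud CSV must have columns x, y, z: ", path, call. = FALSE)
  }
  point_cloud(df, frame_state = frame_state)
}
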