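#' Construct a depth frame
#'
#' A depth frame is an integer matrix of range measurements in millimetres,
#' with `0` as the single "invalid" sentinel (no sensor return). Values above
#' `max_range_mm` are remapped to 0, following the convention of consumer
#' structured-light depth cameras whose measurements become unreliable beyond
#' their rated range.
#'
#' @param depth integer matrix, rows = image rows, depth in mm, 0 = invalid.
#' @param index frame ordinal within its sequence (0-based).
#' @param max_range_mm measurements above this are remapped to 0 (invalid).
#' @return A `depth_frame`: an integer matrix with attributes `index`.
#' @export
depth_frame <- function(depth, index = 0L, max_range_mm = 10000) {
  if (!is.matrix(depth)) stop("depth must be a matrix")
  if (any(depth < 0, na.rm = TRUE)) stop("depth values must be >= 0")
  storage.mode(depth) <- "integer"
  depth[is.na(depth) | depth > max_range_mm] <- 0L
  structure(depth, index = as.integer(index), class = c("depth_frame", "matrix", "array"))
}

#' @export
print.depth_frame <- function(x, ...) {
  lo <- if (any(x > 0L)) min(x[x > 0L]) else 0L
  cat(sprintf("<depth_frame> %dx%d px, index %d, %.1f%% invalid, range [%d, %d] mm\n",
              ncol(x), nrow(x), attr(x, "index"), 100 * mean(x == 0L), lo, max(x)))
  invisible(x)
}

#' Camera intrinsics for a pinhole depth camera
#'
#' @param fx,fy focal lengths in pixels (positive).
#' @param cx,cy principal point in pixels, 0-based image coordinates.
#' @param max_range_mm maximum trusted depth; larger values read as invalid.
#' @return A `camera_model` list.
#' @export
camera_model <- function(fx, fy, cx, cy, max_range_mm = 10000) {
  stopifnot(fx > 0, fy > 0, cx >= 0, cy >= 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, max_range_mm = max_range_mm),
            class = "camera_model")
}

#' Default intrinsics for a 320x240 depth stream
#'
#' Kinect-v1-class intrinsics halved from the 640x480 depth mode:
#' fx = fy = 285.6, principal point at the image centre. All values are
#' overridable through the `camera` config block.
#'
#' @param width,height frame size in pixels.
#' @return A `camera_model`.
#' @export
default_camera <- function(width = 320L, height = 240L) {
  s <- width / 320
  camera_model(fx = 285.6 * s, fy = 285.6 * s,
               cx = (width - 1) / 2, cy = (height - 1) / 2)
}

#' Back-project pixels to camera-world coordinates
#'
#' Pinhole model: X = (u - cx) d / fx, Y = (v - cy) d / fy, Z = d, with the
#' camera at the origin, X right, Y down (image convention), Z along the
#' optical axis, all in millimetres.
#'
#' @param cam a [camera_model()].
#' @param u,v pixel column/row (0-based, continuous allowed); vectorized.
#' @param d depth in mm; must be > 0.
#' @return numeric matrix with columns `X`, `Y`, `Z` (mm), one row per input.
#' @export
pixel_to_world <- function(cam, u, v, d) {
  if (any(d <= 0)) stop("invalid depth: d must be > 0 for back-projection")
  cbind(X = (u - cam$cx) * d / cam$fx,
        Y = (v - cam$cy) * d / cam$fy,
        Z = as.numeric(d))
}

#' Project camera-world points to pixel coordinates
#'
#' Exact inverse of [pixel_to_world()]; returns continuous (unrounded) pixel
#' coordinates.
#'
#' @param cam a [camera_model()].
#' @param p numeric matrix with columns X, Y, Z (mm), or a length-3 vector.
#' @return numeric matrix with columns `u`, `v`, `d`.
#' @export
world_to_pixel <- function(cam, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (any(p[, 3] <= 0)) stop("behind-camera: Z must be > 0 for projection")
  cbind(u = p[, 1] * cam$fx / p[, 3] + cam$cx,
        v = p[, 2] * cam$fy / p[, 3] + cam$cy,
        d = p[, 3])
}

.read_png_depth <- function(path, max_range_mm) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 16L)
    stop(sprintf("format error: %s is %d-bit, expected 16-bit grayscale",
                 basename(path), info$bit.depth))
  if (length(dim(img)) != 2L)
    stop(sprintf("format error: %s is not single-channel", basename(path)))
  m <- round(img * 65535)
  storage.mode(m) <- "integer"
  attributes(m) <- list(dim = dim(m))
  m
}

#' Read a depth-frame sequence
#'
#' Accepts either a directory of 16-bit grayscale PNG frames (read in
#' filename-lexicographic order) or a raw stack file (little-endian header of
#' width, height, count as 4-byte unsigned integers followed by row-major
#' 16-bit frames). Frames are indexed consecutively from 0 and out-of-range
#' values are remapped to 0 (invalid).
#'
#' @param path directory of PNGs or a stack file.
#' @param max_range_mm depth ceiling; larger values become invalid.
#' @return list of [depth_frame()]s, class `depth_sequence`.
#' @export
read_depth_sequence <- function(path, max_range_mm = 10000) {
  if (!file.exists(path)) stop("missing path: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    mats <- lapply(files, .read_png_depth, max_range_mm = max_range_mm)
  } else {
    mats <- .read_stack(path)
  }
  if (length(mats) > 1L) {
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      nm <- if (dir.exists(path)) basename(files[bad]) else sprintf("frame %d", bad - 1L)
      stop("dimension mismatch in sequence at ", nm)
    }
  }
  frames <- lapply(seq_along(mats), function(i)
    depth_frame(mats[[i]], index = i - 1L, max_range_mm = max_range_mm))
  structure(frames, class = "depth_sequence")
}

#' Write a depth-frame sequence
#'
#' PNG mode writes `frame_%06d.png` 16-bit grayscale files into a directory;
#' stack mode writes the raw binary stack format. Round-trips with
#' [read_depth_sequence()] are bit-exact.
#'
#' @param frames list of depth frames (integer matrices).
#' @param path output directory (`format = "png"`) or file (`format = "stack"`).
#' @param format `"png"` or `"stack"`.
#' @export
write_depth_sequence <- function(frames, path, format = c("png", "stack")) {
  format <- match.arg(format)
  if (length(frames) > 1L) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims != dims[, 1])) stop("frames must share dimensions")
  }
  if (format == "png") {
    if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
      stop("unwritable path: ", path)
    for (i in seq_along(frames)) {
      .write_png16(unclass(frames[[i]]),
                   file.path(path, sprintf("frame_%06d.png", i - 1L)))
    }
  } else {
    .write_stack(frames, path)
  }
  invisible(path)
}

.write_stack <- function(frames, path) {
  con <- tryCatch(file(path, "wb"), error = function(e) stop("unwritable path: ", path))
  on.exit(close(con))
  h <- if (length(frames)) nrow(frames[[1]]) else 0L
  w <- if (length(frames)) ncol(frames[[1]]) else 0L
  writeBin(as.integer(c(w, h, length(frames))), con, size = 4L, endian = "little")
  for (f in frames) {
    writeBin(as.integer(t(unclass(f))), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  w <- hdr[1]; h <- hdr[2]; n <- hdr[3]
  lapply(seq_len(n), function(i) {
    v <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
                 endian = "little")
    matrix(v, nrow = h, ncol = w, byrow = TRUE)
  })
}
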