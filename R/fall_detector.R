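#' Robust representative depth of a region
#'
#' Depth readings over a body region are contaminated by background leakage
#' and sensor noise, so the region depth is taken from a Gaussian fitted to
#' the dominant histogram mode: valid depths are binned at 10 mm, values
#' within 200 mm of the modal bin are kept, and the sample mean/deviation is
#' re-estimated once after trimming to 2 deviations. The fitted mean is
#' returned.
#'
#' @param frame a depth frame (or integer matrix).
#' @param region logical mask of the same dimensions, or a bbox
#'   `c(u0, v0, u1, v1)` (0-based inclusive).
#' @param bin_mm histogram bin width (default 10 mm).
#' @param window_mm half-width of the fit window around the mode (default 200 mm).
#' @return depth in mm (numeric scalar).
#' @export
representative_depth <- function(frame, region, bin_mm = 10, window_mm = 200) {
  m <- unclass(frame)
  vals <- if (is.matrix(region) && is.logical(region)) {
    m[region]
  } else {
    b <- round(region)
    m[(b[2]:b[4]) + 1L, (b[1]:b[3]) + 1L]
  }
  vals <- vals[vals > 0L]
  if (length(vals) < 10L) stop("insufficient data: fewer than 10 valid pixels in region")
  bins <- floor(vals / bin_mm)
  tab <- table(bins)
  mode_center <- (as.numeric(names(tab)[which.max(tab)]) + 0.5) * bin_mm
  sel <- vals[abs(vals - mode_center) <= window_mm]
  mu <- mean(sel)
  s <- stats::sd(sel)
  if (is.finite(s) && s > 0) {
    keep <- sel[abs(sel - mu) <= 2 * s]
    if (length(keep) > 0L) mu <- mean(keep)
  }
  mu
}

#' Height of the tracked head above the floor
#'
#' The head's 3-D position is the tracked pixel centre back-projected at the
#' representative depth of the head bounding box (intersected with the
#' silhouette when that intersection holds enough valid pixels); its height is
#' the point-to-plane distance to the floor.
#'
#' @param plane a `floor_plane`.
#' @param cam a `camera_model`.
#' @param center tracked head centre `c(u, v)` (0-based pixels).
#' @param frame the current depth frame.
#' @param bbox head bounding box `c(u0, v0, u1, v1)` (0-based inclusive).
#' @param mask optional silhouette mask to intersect with the box.
#' @return list with `height` (mm) and `point` (1x3 world matrix).
#' @export
head_height <- function(plane, cam, center, frame, bbox, mask = NULL) {
  b <- round(bbox)
  b[c(1, 3)] <- pmin(pmax(b[c(1, 3)], 0), ncol(frame) - 1L)
  b[c(2, 4)] <- pmin(pmax(b[c(2, 4)], 0), nrow(frame) - 1L)
  d <- NULL
  if (!is.null(mask)) {
    box <- matrix(FALSE, nrow(frame), ncol(frame))
    box[(b[2]:b[4]) + 1L, (b[1]:b[3]) + 1L] <- TRUE
    inter <- box & mask
    if (sum(unclass(frame)[inter] > 0L) >= 10L)
      d <- representative_depth(frame, inter)
  }
  if (is.null(d)) d <- representative_depth(frame, b)
  p <- pixel_to_world(cam, center[[1]], center[[2]], d)
  list(height = point_height(plane, p), point = p)
}

#' Initialize the fall-decision state
#'
#' The decision threshold adapts to the subject: it is fixed at one quarter of
#' the first computed head height, so taller and shorter subjects get
#' proportionate thresholds. A fall is declared when head height and centroid
#' height are both below the threshold for `debounce` consecutive qualifying
#' frames (default 1: a single simultaneous frame).
#'
#' @param debounce consecutive qualifying frames required (default 1).
#' @return A `fall_state`.
#' @export
fall_state <- function(debounce = 1L) {
  structure(list(h_head_1 = NA_real_, threshold = NA_real_,
                 status = "no-subject", fall_frame = NA_integer_,
                 counter = 0L, debounce = as.integer(debounce),
                 h_head_series = numeric(0), h_centroid_series = numeric(0),
                 frames = integer(0), events = list()),
            class = "fall_state")
}

#' Advance the fall decision by one frame
#'
#' Implements the adaptive two-stage rule. The first call fixes
#' `threshold = 0.25 * h_head_1`. On later frames, if the head height is at or
#' above the threshold the centroid is *not* evaluated (`centroid_provider` is
#' never called — the second judgment is lazy); if the head height is below
#' the threshold the centroid height is computed, and only when it too is
#' below the threshold does the debounce counter advance. Reaching the
#' debounce count declares a fall (absorbing within a sequence) and records a
#' `fall_event`.
#'
#' @param state a [fall_state()].
#' @param frame_index current frame ordinal.
#' @param head_h head height in mm.
#' @param centroid_provider zero-argument function returning the centroid
#'   height in mm; called only when needed.
#' @return the updated `fall_state`.
#' @export
fall_step <- function(state, frame_index, head_h, centroid_provider) {
  if (state$status == "fall")
    stop("contract error: fall_step() called after a fall was declared")
  if (is.na(state$h_head_1)) {
    state$h_head_1 <- head_h
    state$threshold <- 0.25 * head_h
    state$status <- "tracking"
  }
  state$h_head_series <- c(state$h_head_series, head_h)
  state$frames <- c(state$frames, as.integer(frame_index))
  cent_h <- NA_real_
  if (head_h < state$threshold) {
    cent_h <- centroid_provider()
    if (is.finite(cent_h) && cent_h < state$threshold) {
      state$counter <- state$counter + 1L
    } else {
      state$counter <- 0L
    }
  } else {
    state$counter <- 0L
  }
  state$h_centroid_series <- c(state$h_centroid_series, cent_h)
  if (state$counter >= state$debounce) {
    state$status <- "fall"
    state$fall_frame <- as.integer(frame_index)
    state$events <- c(state$events, list(structure(
      list(frame = as.integer(frame_index), head_height = head_h,
           centroid_height = cent_h, threshold = state$threshold),
      class = "fall_event")))
  }
  state
}

#' @export
print.fall_state <- function(x, ...) {
  cat(sprintf("<fall_state> status %s, threshold %.0f mm (0.25 x %.0f), %d frames, %d event(s)\n",
              x$status, x$threshold, x$h_head_1, length(x$h_head_series),
              length(x$events)))
  invisible(x)
}

#' @export
print.fall_event <- function(x, ...) {
  cat(sprintf("<fall_event> frame %d: head %.0f mm, centroid %.0f mm, threshold %.0f mm\n",
              x$frame, x$head_height, x$centroid_height, x$threshold))
  invisible(x)
}
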