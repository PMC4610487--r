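#' Ellipse parameters for head localization
#'
#' The head is modelled by three concentric ellipses: the central ellipse with
#' semi-axes `(a, b)`, an inner ellipse at 3/4 scale and an outer ellipse at
#' 5/4 scale. The fit score walks outward normal segments between the inner
#' and outer ellipse.
#'
#' @param center numeric `c(u, v)` pixel centre (0-based).
#' @param a,b semi-axes in pixels along x and y (positive).
#' @param theta orientation in radians, `[0, pi)`.
#' @return An `ellipse_params` list.
#' @export
ellipse_params <- function(center, a, b, theta = 0) {
  stopifnot(a > 0, b > 0, theta >= 0, theta < pi)
  structure(list(center = c(u = center[[1]], v = center[[2]]),
                 a = a, b = b, theta = theta),
            class = "ellipse_params")
}

# sample offsets for one (a, b, theta): list with du, dv (n_seg x n_samp
# matrices of offsets from the ellipse centre), D (per-segment half-length,
# px), s (radial scale of each sample column)
.ellipse_offsets <- function(a, b, theta, n_segments, step = 0.25) {
  t <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  ex <- a * cos(t)
  ey <- b * sin(t)
  r <- sqrt(ex^2 + ey^2)            # radial extent of the central ellipse
  D <- 0.25 * r                     # half of the inner-to-outer segment
  n_samp <- max(9L, ceiling(0.5 * max(r) / step) + 1L)
  s <- seq(0.75, 1.25, length.out = n_samp)
  ct <- cos(theta); st <- sin(theta)
  du <- outer(ex * ct - ey * st, s)
  dv <- outer(ex * st + ey * ct, s)
  list(du = du, dv = dv, D = D, s = s)
}

#' Foreground coefficient of an ellipse against a silhouette
#'
#' Samples `n_segments` points uniformly in parametric angle on the central
#' ellipse and walks each outward normal segment from the inner (3/4) to the
#' outer (5/4) ellipse. With `D` the half-length of the segment and `d` the
#' distance from the central-ellipse point to the silhouette boundary crossing
#' along it (clamped to `D` when no crossing exists), the score is
#' `C = mean((D - d)/D)`, clamped to `[0, 1]`. `C` is maximal when the
#' silhouette boundary lies on the central ellipse at every sampled normal.
#'
#' @param mask logical silhouette matrix.
#' @param e an [ellipse_params()].
#' @param n_segments number of normal segments (>= 8; default 40).
#' @return scalar score in `[0, 1]`.
#' @export
foreground_coefficient <- function(mask, e, n_segments = 40L) {
  if (n_segments < 8L) stop("n_segments must be >= 8")
  off <- .ellipse_offsets(e$a, e$b, e$theta, n_segments)
  h <- nrow(mask); w <- ncol(mask)
  u0 <- e$center[["u"]]; v0 <- e$center[["v"]]
  if (u0 - 1.25 * e$a < -0.5 || u0 + 1.25 * e$a > w - 0.5 ||
      v0 - 1.25 * e$b < -0.5 || v0 + 1.25 * e$b > h - 0.5)
    stop("ellipse out of bounds")
  .fg_coef(mask, u0, v0, off)
}

# core score given precomputed offsets; used by the search loop
.fg_coef <- function(mask, u0, v0, off) {
  h <- nrow(mask); w <- ncol(mask)
  cc <- pmin(pmax(round(u0 + off$du), 0), w - 1)   # clamp: outside = background
  rr <- pmin(pmax(round(v0 + off$dv), 0), h - 1)
  vals <- matrix(mask[cbind(as.vector(rr) + 1L, as.vector(cc) + 1L)],
                 nrow = nrow(off$du))
  n_samp <- ncol(vals)
  chg <- vals[, -1L, drop = FALSE] != vals[, -n_samp, drop = FALSE]
  s_mid <- (off$s[-1L] + off$s[-n_samp]) / 2
  # distance from the central point (scale 1) to the nearest crossing
  dist_s <- abs(matrix(s_mid, nrow(chg), ncol(chg), byrow = TRUE) - 1)
  dist_s[!chg] <- NA
  dmin_s <- suppressWarnings(apply(dist_s, 1L, min, na.rm = TRUE))
  dmin_s[!is.finite(dmin_s)] <- 0.25               # no crossing: d = D
  r <- off$D / 0.25
  d <- dmin_s * r
  mean(pmin(pmax((off$D - d) / off$D, 0), 1))
}

#' Locate the head in a silhouette
#'
#' Grid search for the ellipse maximizing the foreground coefficient:
#' candidate centres on a stride-`stride` grid over foreground pixels in the
#' top 40% (by bounding-box height) of the silhouette — heads sit near the top
#' of the silhouette in every pre-fall frame, which is the only place this
#' detector runs — with semi-axis `a` stepping through `radius_range` and
#' aspect ratios `b/a` in `ratios`, orientation fixed at 0. Ties are broken by
#' smaller row (higher in the image), then smaller column.
#'
#' @param mask logical silhouette matrix (non-empty).
#' @param radius_range `c(min, max)` candidate semi-axis `a` in pixels.
#' @param ratios candidate aspect ratios `b/a`.
#' @param n_segments normal segments for the score (default 40).
#' @param min_score minimum acceptable score; below it the head is declared
#'   not found. On a rasterized mask each normal loses about `D/8` to pixel
#'   quantization and the body occludes the lower arc of a real head, so a
#'   correct head-and-shoulders fit scores about 0.5; headless convex blobs
#'   score below about 0.3. The default 0.4 separates the two.
#' @param stride centre grid stride in pixels.
#' @return A `head_candidate`: list with `ellipse`, `score` and `bbox`
#'   (`c(u0, v0, u1, v1)`, 0-based inclusive, enclosing the outer ellipse).
#' @export
locate_head <- function(mask, radius_range = c(5, 14), ratios = c(1, 1.2, 1.3),
                        n_segments = 40L, min_score = 0.4, stride = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no subject: empty silhouette mask")
  h <- nrow(mask); w <- ncol(mask)
  v_top <- min(idx[, 1]) - 1L
  v_bot <- max(idx[, 1]) - 1L
  # top 40% of the silhouette, but never shallower than the largest candidate
  # radius so an isolated head blob keeps its own centre in the band
  band_depth <- max(0.4 * (v_bot - v_top), radius_range[2])
  band <- idx[idx[, 1] - 1L <= v_top + band_depth, , drop = FALSE]
  keep <- ((band[, 1] - 1L) %% stride == 0L) & ((band[, 2] - 1L) %% stride == 0L)
  cand <- band[keep, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- band[1, , drop = FALSE]
  a_vals <- seq(radius_range[1], radius_range[2], by = 1)
  best <- list(score = -Inf, u = NA, v = NA, a = NA, b = NA)
  for (a in a_vals) {
    for (rat in ratios) {
      b <- a * rat
      off <- .ellipse_offsets(a, b, 0, n_segments)
      ok <- cand[, 2] - 1L - 1.25 * a >= -0.5 & cand[, 2] - 1L + 1.25 * a <= w - 0.5 &
            cand[, 1] - 1L - 1.25 * b >= -0.5 & cand[, 1] - 1L + 1.25 * b <= h - 0.5
      for (i in which(ok)) {
        u0 <- cand[i, 2] - 1L; v0 <- cand[i, 1] - 1L
        sc <- .fg_coef(mask, u0, v0, off)
        if (sc > best$score + 1e-12 ||
            (abs(sc - best$score) <= 1e-12 &&
             (v0 < best$v || (v0 == best$v && u0 < best$u)))) {
          best <- list(score = sc, u = u0, v = v0, a = a, b = b)
        }
      }
    }
  }
  if (!is.finite(best$score) || best$score < min_score)
    stop(sprintf("head not found: best foreground coefficient %.3f < %.2f",
                 max(best$score, 0), min_score))
  e <- ellipse_params(c(best$u, best$v), best$a, best$b, 0)
  bbox <- c(u0 = max(0L, floor(best$u - 1.25 * best$a)),
            v0 = max(0L, floor(best$v - 1.25 * best$b)),
            u1 = min(w - 1L, ceiling(best$u + 1.25 * best$a)),
            v1 = min(h - 1L, ceiling(best$v + 1.25 * best$b)))
  structure(list(ellipse = e, score = best$score, bbox = bbox),
            class = "head_candidate")
}
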