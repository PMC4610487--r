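#' Fit a floor plane by least squares
#'
#' The floor is modelled as `A X + B Y + C Z = 1` in camera-world millimetre
#' coordinates (the "= 1" form excludes planes through the camera origin).
#' Coefficients minimize the sum of squared residuals
#' `sum (A X_i + B Y_i + C Z_i - 1)^2`, solved through the normal equations.
#'
#' @param points numeric matrix with columns X, Y, Z (mm); at least 3
#'   non-collinear rows.
#' @param inlier_tol residual bound for [plane_inliers()] (dimensionless,
#'   default 0.05).
#' @return A `floor_plane`: list with `A`, `B`, `C` (1/mm) and `inlier_tol`.
#' @export
fit_plane <- function(points, inlier_tol = 0.05) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (nrow(points) < 3L) stop("degenerate geometry: need at least 3 points")
  M <- points[, 1:3, drop = FALSE]
  G <- crossprod(M)
  if (rcond(G) < 1e-14)
    stop("degenerate geometry: collinear points or plane through the origin")
  coef <- solve(G, colSums(M))
  structure(list(A = coef[[1]], B = coef[[2]], C = coef[[3]],
                 inlier_tol = inlier_tol),
            class = "floor_plane")
}

#' @export
print.floor_plane <- function(x, ...) {
  cat(sprintf("<floor_plane> %.6g X + %.6g Y + %.6g Z = 1 (1/mm), inlier tol %.3g\n",
              x$A, x$B, x$C, x$inlier_tol))
  invisible(x)
}

#' Classify points as floor-plane inliers
#'
#' A point belongs to the floor when its dimensionless residual
#' `|A X + B Y + C Z - 1|` is strictly smaller than the tolerance (0.05 by
#' default). Because A, B, C carry 1/mm, the bound is unit-free.
#'
#' @param plane a [fit_plane()] result.
#' @param points numeric matrix with columns X, Y, Z.
#' @return logical vector, one flag per point.
#' @export
plane_inliers <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- abs(points[, 1] * plane$A + points[, 2] * plane$B +
           points[, 3] * plane$C - 1)
  unname(r < plane$inlier_tol)
}

#' Height of a point above the floor plane
#'
#' Point-to-plane distance `H = |A X + B Y + C Z - 1| / sqrt(A^2 + B^2 + C^2)`
#' in millimetres; always non-negative, zero exactly on the plane.
#'
#' @param plane a `floor_plane`.
#' @param p numeric matrix with columns X, Y, Z (or a length-3 vector).
#' @return numeric vector of heights in mm.
#' @export
point_height <- function(plane, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  unname(abs(p[, 1] * plane$A + p[, 2] * plane$B + p[, 3] * plane$C - 1) /
           sqrt(plane$A^2 + plane$B^2 + plane$C^2))
}

#' Estimate the floor plane from a designated depth region
#'
#' Back-projects every valid pixel of the background mean-depth map that lies
#' inside the user-designated region of interest, fits the plane by least
#' squares, then classifies every valid pixel of the full map with
#' [plane_inliers()] to produce the floor mask. The ROI defines "floor": a
#' region placed on a wall fits the wall and all heights are measured from it.
#'
#' @param bg a `gauss_background` (its `mu` map is used), or a depth frame.
#' @param roi polygon as a matrix/list of `(u, v)` pixel vertices (0-based).
#' @param cam a [camera_model()].
#' @param inlier_tol residual bound (default 0.05).
#' @return list with `plane` (a `floor_plane`) and `mask` (logical floor mask).
#' @export
extract_floor <- function(bg, roi, cam, inlier_tol = 0.05) {
  depth <- if (inherits(bg, "gauss_background")) {
    d <- bg$mu
    d[!bg$valid] <- 0
    d
  } else {
    unclass(bg)
  }
  if (is.list(roi) && !is.matrix(roi)) roi <- do.call(rbind, roi)
  roi <- as.matrix(roi)
  h <- nrow(depth); w <- ncol(depth)
  uu <- matrix(rep(0:(w - 1), each = h), h, w)
  vv <- matrix(rep(0:(h - 1), times = w), h, w)
  inside <- matrix(mgcv::in.out(rbind(roi, roi[1, ]),
                                cbind(as.vector(uu), as.vector(vv))), h, w)
  sel <- inside & depth > 0
  if (sum(sel) < 3L) stop("degenerate roi: fewer than 3 valid depth pixels")
  pts <- pixel_to_world(cam, uu[sel], vv[sel], depth[sel])
  plane <- fit_plane(pts, inlier_tol = inlier_tol)
  valid <- depth > 0
  allpts <- pixel_to_world(cam, uu[valid], vv[valid], depth[valid])
  mask <- matrix(FALSE, h, w)
  mask[valid] <- plane_inliers(plane, allpts)
  list(plane = plane, mask = mask)
}
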