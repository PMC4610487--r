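test_that("least squares recovers exact planes and survives noise", {
  set.seed(4)
  # noiseless Y = 1000 mm
  pts <- cbind(X = runif(200, -2000, 2000), Y = 1000, Z = runif(200, 1000, 6000))
  pl <- fit_plane(pts)
  expect_equal(c(pl$A, pl$B, pl$C), c(0, 0.001, 0), tolerance = 1e-12)

  # 3 exact points interpolate with zero residual
  p3 <- cbind(c(100, -500, 800), c(900, 1100, 1000), c(2000, 3000, 4000))
  pl3 <- fit_plane(p3)
  res <- p3 %*% c(pl3$A, pl3$B, pl3$C) - 1
  expect_lt(max(abs(res)), 1e-10)

  # 1e4 noisy points at sigma = 10 mm recover B within 1%
  ptsn <- cbind(X = runif(1e4, -2000, 2000), Y = 1000 + rnorm(1e4, 0, 10),
                Z = runif(1e4, 1000, 6000))
  pln <- fit_plane(ptsn)
  expect_lt(abs(pln$B - 0.001) / 0.001, 0.01)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_plane(cbind(1:2, 1:2, 1:2)), "at least 3")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))          # collinear through origin
  expect_error(fit_plane(line), "degenerate")
  origin_plane <- cbind(X = runif(50, -1000, 1000), Y = 0, Z = runif(50, 500, 5000))
  expect_error(fit_plane(origin_plane), "degenerate")  # Y = 0 passes the origin
})

test_that("normal-equation residuals are orthogonal to the design columns", {
  set.seed(15)
  pts <- cbind(runif(500, -2000, 2000), 1000 + rnorm(500, 0, 25),
               runif(500, 500, 6000))
  pl <- fit_plane(pts)
  r <- pts %*% c(pl$A, pl$B, pl$C) - 1
  expect_lt(max(abs(crossprod(pts, r))) / nrow(pts), 1e-8)
})

test_that("inlier rule is the strict dimensionless 0.05 bound", {
  pl <- structure(list(A = 0, B = 0.001, C = 0, inlier_tol = 0.05),
                  class = "floor_plane")
  expect_true(plane_inliers(pl, c(0, 1000, 0)))        # residual 0
  expect_true(plane_inliers(pl, c(0, 1049, 0)))        # residual 0.049
  expect_false(plane_inliers(pl, c(0, 1051, 0)))       # residual 0.051
  expect_false(plane_inliers(pl, c(0, 1050, 0)))       # exactly 0.05: strict
})

test_that("point heights are the point-to-plane distance in millimetres", {
  pl <- structure(list(A = 0, B = 0.001, C = 0, inlier_tol = 0.05),
                  class = "floor_plane")
  expect_equal(point_height(pl, c(123, 1000, 4567)), 0)
  expect_equal(point_height(pl, c(0, 2000, 0)), 1000)
  expect_gte(min(point_height(pl, cbind(runif(50), runif(50, 0, 3000), runif(50)))), 0)
})

test_that("heights are invariant under rigid motion of scene plus query", {
  set.seed(21)
  pts <- cbind(runif(300, -1500, 1500), 1200, runif(300, 800, 5000))
  q <- c(300, 400, 2500)
  h0 <- point_height(fit_plane(pts), q)
  for (k in 1:5) {
    th <- runif(3, -pi, pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rx %*% Rz
    shift <- matrix(runif(3, -500, 500), 1)
    ptsr <- pts %*% t(R) + shift[rep(1, nrow(pts)), ]
    qr <- as.numeric(q %*% t(R)) + as.numeric(shift)
    hr <- point_height(fit_plane(ptsr), qr)
    expect_equal(hr, h0, tolerance = 1e-6)
  }
})

test_that("floor extraction from a designated region recovers the scene floor", {
  scene <- test_scene(noise_sigma = 5)
  bgr <- render_background(scene, 10)
  bg <- fit_background(bgr$frames, sigma_min = 5)
  roi <- scene_floor_roi(scene)
  fl <- extract_floor(bg, roi, scene$cam)
  truth <- true_floor_plane(scene)
  tv <- c(truth$A, truth$B, truth$C)
  expect_lt(max(abs(c(fl$plane$A, fl$plane$B, fl$plane$C) - tv)) / max(abs(tv)), 0.01)
  iou <- sum(fl$mask & bgr$floor_mask) / sum(fl$mask | bgr$floor_mask)
  expect_gte(iou, 0.95)
})

test_that("the ROI defines the reference surface even when placed on a wall", {
  scene <- test_scene(noise_sigma = 0, invalid_rate = 0)
  bgr <- render_background(scene, 3)
  bg <- fit_background(bgr$frames, sigma_min = 5)
  wall_roi <- cbind(u = c(100, 220, 220, 100), v = c(5, 5, 40, 40))
  expect_false(any(bgr$floor_mask[(5:40) + 1L, (100:220) + 1L]))
  fl <- extract_floor(bg, wall_roi, scene$cam)
  # heights are now measured from the wall: a wall point sits at height ~0
  wall_pt <- pixel_to_world(scene$cam, 160, 20, unclass(bgr$frames[[1]])[21, 161])
  expect_lt(point_height(fl$plane, wall_pt), 30)
  # and a nearby floor point is far from the "floor" surface
  fidx <- which(bgr$floor_mask, arr.ind = TRUE)
  floor_px <- fidx[which.max(fidx[, 1]), ]
  fp <- pixel_to_world(scene$cam, floor_px[2] - 1, floor_px[1] - 1,
                       unclass(bgr$frames[[1]])[floor_px[1], floor_px[2]])
  expect_gt(point_height(fl$plane, fp), 300)
})

test_that("an ROI with too few valid pixels is rejected", {
  scene <- test_scene()
  bgr <- render_background(scene, 3)
  bg <- fit_background(bgr$frames, sigma_min = 5)
  tiny <- cbind(u = c(10, 11, 11, 10), v = c(200, 200, 200.4, 200.4))
  expect_error(extract_floor(bg, tiny, scene$cam), "degenerate roi")
})
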