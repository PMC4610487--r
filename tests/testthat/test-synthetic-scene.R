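test_that("background rendering is seeded, deterministic, and noise-calibrated", {
  scene <- test_scene(noise_sigma = 0, invalid_rate = 0)
  bgr <- render_background(scene, 3)
  expect_identical(as.integer(bgr$frames[[1]]), as.integer(bgr$frames[[3]]))

  scene_n <- test_scene(noise_sigma = 10)
  a <- render_background(scene_n, 2)
  b <- render_background(scene_n, 2)
  expect_identical(unclass(a$frames[[1]]), unclass(b$frames[[1]]))
  expect_identical(unclass(a$frames[[2]]), unclass(b$frames[[2]]))

  # per-pixel deviation over many frames matches noise_sigma within 15%
  many <- render_background(scene_n, 100)
  stack <- vapply(many$frames, function(f) unclass(f)[101:140, 141:180],
                  matrix(0L, 40, 40))
  sds <- apply(stack, c(1, 2), function(x) sd(x[x > 0]))
  expect_lt(abs(median(sds, na.rm = TRUE) - 10) / 10, 0.15)
})

test_that("rendered floor pixels satisfy the configured plane equation", {
  scene <- test_scene(noise_sigma = 0, invalid_rate = 0)
  bgr <- render_background(scene, 1)
  truth <- true_floor_plane(scene)
  idx <- which(bgr$floor_mask, arr.ind = TRUE)
  sel <- idx[seq(1, nrow(idx), length.out = 500), ]
  d <- unclass(bgr$frames[[1]])[sel]
  pts <- pixel_to_world(scene$cam, sel[, 2] - 1, sel[, 1] - 1, d)
  # quantized to 1 mm, so heights are within 1 mm of zero
  expect_lt(max(point_height(truth, pts)), 1.01)
})

test_that("ground-truth heights agree with an independent height formula", {
  scene <- test_scene()
  act <- render_activity(scene, activity_script("fall", "left", n_frames = 30,
                                                start_frame = 5,
                                                duration_frames = 20))
  gt <- act$gt
  phi <- scene$tilt_deg * pi / 180
  # independent: height above floor = camera height - world-down coordinate
  h_indep <- scene$camera_height_mm - (gt$head_Y * cos(phi) + gt$head_Z * sin(phi))
  expect_equal(gt$head_h, h_indep, tolerance = 1e-6)
  c_indep <- scene$camera_height_mm - (gt$cent_Y * cos(phi) + gt$cent_Z * sin(phi))
  expect_equal(gt$cent_h, c_indep, tolerance = 1e-6)
})

test_that("activity kinematics follow the scripts", {
  scene <- test_scene()
  stand <- render_activity(scene, activity_script("stand", n_frames = 6))
  expect_equal(diff(range(stand$gt$head_h)), 0)

  fall <- render_activity(scene, activity_script("fall", "anterior", n_frames = 40,
                                                 start_frame = 8,
                                                 duration_frames = 25))
  expect_true(all(diff(fall$gt$head_h) <= 1e-9))           # monotone descent
  expect_lt(fall$gt$head_h[40], 2 * 110)                   # below head diameter
  expect_identical(fall$fall_frame, 33L)
  expect_equal(fall$gt$theta[34:40], rep(max(fall$gt$theta), 7))

  left <- render_activity(scene, activity_script("fall", "left", n_frames = 40,
                                                 start_frame = 8,
                                                 duration_frames = 25))
  expect_equal(left$gt$head_h, fall$gt$head_h, tolerance = 1e-9)
  expect_gt(max(abs(left$gt$head_u - fall$gt$head_u)), 20)  # different pixel paths

  # a subject too close to the camera exits the frustum mid-fall
  near <- activity_script("fall", "anterior", n_frames = 40, start_frame = 2,
                          duration_frames = 30,
                          subject = list(ground_dist = 1700))
  expect_error(render_activity(scene, near), "subject leaves frame")
})

test_that("the benchmark fixture has the scripted shape and reproduces bit-identically", {
  bm <- make_benchmark(seed = 3, n_background = 3, n_frames = 4)
  expect_named(bm$sequences,
               c("anterior", "posterior", "left", "right", "walk", "sit"))
  falls <- bm$sequences[c("anterior", "posterior", "left", "right")]
  for (s in falls) expect_false(is.na(s$fall_frame))
  for (s in bm$sequences[c("walk", "sit")]) expect_true(is.na(s$fall_frame))
  expect_length(bm$background$frames, 3L)

  bm2 <- make_benchmark(seed = 3, n_background = 3, n_frames = 4)
  expect_identical(unclass(bm$sequences$left$frames[[2]]),
                   unclass(bm2$sequences$left$frames[[2]]))
  expect_identical(unclass(bm$background$frames[[1]]),
                   unclass(bm2$background$frames[[1]]))
})
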