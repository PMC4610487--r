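# Synthetic depth-scene simulator with analytic ground truth.
#
# Emulates the experimental setup the pipeline targets: a depth camera mounted
# at 1.2 m with a slight downward tilt viewing a room (floor + back wall), and
# a single person who stands, walks, sits, or falls in one of four
# orientations (anterior = toward the camera, posterior, left, right). The
# subject is modelled as an ellipsoid head on a box torso/legs, rigidly
# rotated about a pivot at the feet during a fall, so head/centroid positions
# and heights are available in closed form every frame.

#' Scene configuration for the synthetic renderer
#'
#' @param width,height frame size in pixels.
#' @param camera_height_mm camera height above the floor (default 1200).
#' @param tilt_deg downward camera tilt (default 12.5).
#' @param wall_dist_mm horizontal distance to the back wall (default 6000).
#' @param noise_sigma depth noise standard deviation in mm (default 10,
#'   first-order consumer-sensor noise at indoor range).
#' @param invalid_rate i.i.d. fraction of pixels zeroed per frame (default 0.01).
#' @param seed integer RNG seed; all rendering is deterministic given it.
#' @param cam optional [camera_model()]; defaults to [default_camera()].
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 320L, height = 240L, camera_height_mm = 1200,
                         tilt_deg = 12.5, wall_dist_mm = 6000,
                         noise_sigma = 10, invalid_rate = 0.01, seed = 1L,
                         cam = NULL) {
  stopifnot(camera_height_mm > 0, invalid_rate >= 0, invalid_rate < 0.2,
            noise_sigma >= 0)
  if (is.null(cam)) cam <- default_camera(width, height)
  structure(list(width = as.integer(width), height = as.integer(height),
                 camera_height_mm = camera_height_mm, tilt_deg = tilt_deg,
                 wall_dist_mm = wall_dist_mm, noise_sigma = noise_sigma,
                 invalid_rate = invalid_rate, seed = as.integer(seed),
                 cam = cam),
            class = "scene_config")
}

#' True floor plane of a synthetic scene
#'
#' Closed-form coefficients of `A X + B Y + C Z = 1` in camera coordinates
#' implied by the camera height and tilt.
#'
#' @param scene a [scene_config()].
#' @return a `floor_plane`.
#' @export
true_floor_plane <- function(scene) {
  phi <- scene$tilt_deg * pi / 180
  structure(list(A = 0, B = cos(phi) / scene$camera_height_mm,
                 C = sin(phi) / scene$camera_height_mm, inlier_tol = 0.05),
            class = "floor_plane")
}

# per-pixel world-frame ray directions (camera z-component = 1, so the ray
# parameter t IS the stored camera depth Z)
.scene_rays <- function(scene) {
  phi <- scene$tilt_deg * pi / 180
  cam <- scene$cam
  h <- scene$height; w <- scene$width
  rx <- matrix(rep((0:(w - 1) - cam$cx) / cam$fx, each = h), h, w)
  ry <- matrix(rep((0:(h - 1) - cam$cy) / cam$fy, times = w), h, w)
  list(x = rx,
       y = ry * cos(phi) + sin(phi),      # world Y (down)
       z = -ry * sin(phi) + cos(phi),     # world Z (horizontal forward)
       phi = phi)
}

# clean (noise-free) background geometry: depth + which-surface
.bg_geometry <- function(scene) {
  r <- .scene_rays(scene)
  t_floor <- ifelse(r$y > 1e-9, scene$camera_height_mm / r$y, Inf)
  t_wall <- ifelse(r$z > 1e-9, scene$wall_dist_mm / r$z, Inf)
  depth <- pmin(t_floor, t_wall)
  list(depth = depth, floor = is.finite(depth) & t_floor < t_wall, rays = r)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# add sensor noise + dropouts and quantize to an integer depth frame
.sensorize <- function(depth, scene) {
  d <- depth
  out <- is.infinite(d) | d > scene$cam$max_range_mm | d <= 0
  d[out] <- 0
  if (scene$noise_sigma > 0) {
    nz <- d > 0
    d[nz] <- d[nz] + rnorm(sum(nz), 0, scene$noise_sigma)
  }
  if (scene$invalid_rate > 0) {
    drop <- runif(length(d)) < scene$invalid_rate
    d[drop] <- 0
  }
  d <- round(pmax(d, 0))
  d[d > scene$cam$max_range_mm] <- 0
  d
}

#' Render background-only frames
#'
#' Z-buffer renders the floor and back wall, then adds Gaussian depth noise
#' and invalid dropouts per frame. Deterministic for a given scene seed.
#'
#' @param scene a [scene_config()].
#' @param n_frames number of frames.
#' @return list with `frames` (list of depth frames), `floor_mask` (logical
#'   ground-truth floor pixels) and `clean_depth` (noise-free geometry, mm).
#' @export
render_background <- function(scene, n_frames) {
  geo <- .bg_geometry(scene)
  if (any(geo$depth <= 0)) stop("camera below floor")
  frames <- .with_seed(scene$seed, {
    lapply(seq_len(n_frames), function(i)
      depth_frame(.sensorize(geo$depth, scene), index = i - 1L,
                  max_range_mm = scene$cam$max_range_mm))
  })
  list(frames = frames, floor_mask = geo$floor, clean_depth = geo$depth)
}

#' Script for one activity sequence
#'
#' @param activity `"stand"`, `"walk"`, `"sit"`, or `"fall"`.
#' @param orientation fall direction relative to the camera: `"anterior"`
#'   (toward it), `"posterior"`, `"left"`, `"right"`.
#' @param n_frames sequence length.
#' @param start_frame frame at which the activity (fall/sit) begins.
#' @param duration_frames frames the activity takes.
#' @param subject anthropometrics, mm: `head_r` (lateral head semi-axis),
#'   `head_rv` (vertical), `head_center` (standing head-centre height),
#'   `torso_w`, `torso_th`, `torso_top`, `ground_dist` (pivot distance from
#'   the camera along the ground), `lateral` (pivot lateral offset).
#' @param walk_span_mm total lateral walk travel (walk activity).
#' @param sit_ratio fraction of standing height when seated (sit activity).
#' @return An `activity_script`.
#' @export
activity_script <- function(activity = c("stand", "walk", "sit", "fall"),
                            orientation = c("anterior", "posterior", "left", "right"),
                            n_frames = 150L, start_frame = 40L,
                            duration_frames = 40L,
                            subject = list(), walk_span_mm = 1200,
                            sit_ratio = 0.66) {
  activity <- match.arg(activity)
  orientation <- match.arg(orientation)
  subj <- utils::modifyList(
    list(head_r = 90, head_rv = 110, head_center = 1600, torso_w = 400,
         torso_th = 250, torso_top = 1520, ground_dist = 3600, lateral = 0),
    subject)
  structure(list(activity = activity, orientation = orientation,
                 n_frames = as.integer(n_frames),
                 start_frame = as.integer(start_frame),
                 duration_frames = as.integer(duration_frames),
                 subject = subj, walk_span_mm = walk_span_mm,
                 sit_ratio = sit_ratio),
            class = "activity_script")
}

.orient_dir <- function(orientation) {
  switch(orientation,
         anterior = c(0, 0, -1), posterior = c(0, 0, 1),
         left = c(-1, 0, 0), right = c(1, 0, 0))
}

.world_to_cam <- function(p, phi) {
  cbind(X = p[, 1],
        Y = p[, 2] * cos(phi) - p[, 3] * sin(phi),
        Z = p[, 2] * sin(phi) + p[, 3] * cos(phi))
}

# pose of the subject at a scripted frame: tilt angle theta, vertical scale
# kappa, pivot lateral offset
.pose_at <- function(script, i) {
  s01 <- function() {
    s <- ((i - 1) - script$start_frame) / script$duration_frames  # 0-based frame
    min(max(s, 0), 1)
  }
  subj <- script$subject
  theta <- 0; kappa <- 1; lat <- subj$lateral
  if (script$activity == "fall") {
    theta_end <- acos(min(0.99, subj$head_rv / subj$head_center))
    theta <- theta_end * s01()^2          # gravity: the fall accelerates
  } else if (script$activity == "sit") {
    kappa <- 1 - (1 - script$sit_ratio) * s01()^2
  } else if (script$activity == "walk") {
    lat <- subj$lateral +
      script$walk_span_mm * ((i - 1) / max(script$n_frames - 1, 1) - 0.5)
  }
  list(theta = theta, kappa = kappa, lat = lat)
}

#' Render an activity sequence with ground truth
#'
#' Composites the humanoid (ellipsoid head + box torso/legs) nearest-surface
#' wins over the background, adds sensor noise, and records analytic
#' ground truth every frame: head centre and body centroid in pixel and
#' camera-world coordinates, their heights above the true floor plane, and —
#' for falls — the fall-completion frame (the first frame at the final rest
#' angle).
#'
#' @param scene a [scene_config()].
#' @param script an [activity_script()].
#' @param keep_masks keep per-frame ground-truth subject masks (memory-heavy;
#'   default `FALSE`).
#' @return list with `frames`, `gt` (tibble, one row per frame; attribute
#'   `fall_frame`), and optionally `masks`.
#' @export
render_activity <- function(scene, script, keep_masks = FALSE) {
  geo <- .bg_geometry(scene)
  r <- geo$rays
  phi <- r$phi
  H <- scene$camera_height_mm
  subj <- script$subject
  Fdir <- .orient_dir(script$orientation)
  U0 <- c(0, -1, 0)
  theta_end <- acos(min(0.99, subj$head_rv / subj$head_center))
  fall_frame <- if (script$activity == "fall") {
    script$start_frame + script$duration_frames
  } else NA_integer_

  frames <- vector("list", script$n_frames)
  masks <- if (keep_masks) vector("list", script$n_frames) else NULL
  gt_rows <- vector("list", script$n_frames)
  plane <- true_floor_plane(scene)

  .with_seed(scene$seed + 7L, {
    for (i in seq_len(script$n_frames)) {
      pose <- .pose_at(script, i)
      ct <- cos(pose$theta); st <- sin(pose$theta)
      e_up <- U0 * ct + Fdir * st
      e_f <- Fdir * ct - U0 * st
      e_l <- c(e_up[2] * e_f[3] - e_up[3] * e_f[2],
               e_up[3] * e_f[1] - e_up[1] * e_f[3],
               e_up[1] * e_f[2] - e_up[2] * e_f[1])
      pivot <- c(pose$lat, H, subj$ground_dist)
      o <- -pivot                      # camera origin in pivot-centred world
      o_b <- c(sum(o * e_l), sum(o * e_f), sum(o * e_up))
      d_l <- r$x * e_l[1] + r$y * e_l[2] + r$z * e_l[3]
      d_f <- r$x * e_f[1] + r$y * e_f[2] + r$z * e_f[3]
      d_u <- r$x * e_up[1] + r$y * e_up[2] + r$z * e_up[3]

      # box torso/legs: |l| <= w/2, |f| <= th/2, 0 <= up <= kappa*torso_top
      top <- pose$kappa * subj$torso_top
      t_box <- .ray_box(o_b, d_l, d_f, d_u,
                        c(-subj$torso_w / 2, -subj$torso_th / 2, 0),
                        c(subj$torso_w / 2, subj$torso_th / 2, top))
      # ellipsoid head at body (0, 0, kappa*head_center)
      hc <- pose$kappa * subj$head_center
      t_head <- .ray_ellipsoid(o_b - c(0, 0, hc), d_l, d_f, d_u,
                               c(subj$head_r, subj$head_r, subj$head_rv))
      t_subj <- pmin(t_box, t_head)
      submask <- t_subj < geo$depth
      depth <- pmin(geo$depth, t_subj)

      head_w <- pivot + hc * e_up
      cent_body <- .body_centroid(subj, pose$kappa)
      cent_w <- pivot + cent_body * e_up
      pw <- .world_to_cam(rbind(head_w, cent_w), phi)
      px <- world_to_pixel(scene$cam, pw)
      .check_in_frame(scene, script, subj, pose, pivot, e_up, e_f, e_l, phi, i)

      frames[[i]] <- depth_frame(.sensorize(depth, scene), index = i - 1L,
                                 max_range_mm = scene$cam$max_range_mm)
      if (keep_masks) masks[[i]] <- submask
      gt_rows[[i]] <- list(
        frame = i - 1L, theta = pose$theta,
        head_u = px[1, 1], head_v = px[1, 2],
        head_X = pw[1, 1], head_Y = pw[1, 2], head_Z = pw[1, 3],
        head_h = point_height(plane, pw[1, , drop = FALSE]),
        cent_u = px[2, 1], cent_v = px[2, 2],
        cent_X = pw[2, 1], cent_Y = pw[2, 2], cent_Z = pw[2, 3],
        cent_h = point_height(plane, pw[2, , drop = FALSE]))
    }
  })
  gt <- tibble::as_tibble(do.call(rbind.data.frame, gt_rows))
  attr(gt, "fall_frame") <- fall_frame
  out <- list(frames = frames, gt = gt, fall_frame = fall_frame,
              floor_mask = geo$floor)
  if (keep_masks) out$masks <- masks
  out
}

# height of the combined body centroid (volume-weighted) along e_up
.body_centroid <- function(subj, kappa) {
  v_box <- subj$torso_w * subj$torso_th * subj$torso_top * kappa
  v_head <- 4 / 3 * pi * subj$head_r^2 * subj$head_rv
  (v_box * kappa * subj$torso_top / 2 + v_head * kappa * subj$head_center) /
    (v_box + v_head)
}

.ray_box <- function(o, d1, d2, d3, lo, hi) {
  eps <- 1e-12
  f1 <- ifelse(abs(d1) < eps, eps, d1)
  f2 <- ifelse(abs(d2) < eps, eps, d2)
  f3 <- ifelse(abs(d3) < eps, eps, d3)
  a1 <- (lo[1] - o[1]) / f1; b1 <- (hi[1] - o[1]) / f1
  a2 <- (lo[2] - o[2]) / f2; b2 <- (hi[2] - o[2]) / f2
  a3 <- (lo[3] - o[3]) / f3; b3 <- (hi[3] - o[3]) / f3
  tmin <- pmax(pmin(a1, b1), pmin(a2, b2), pmin(a3, b3))
  tmax <- pmin(pmax(a1, b1), pmax(a2, b2), pmax(a3, b3))
  ifelse(tmin <= tmax & tmin > 0, tmin, Inf)
}

.ray_ellipsoid <- function(o, d1, d2, d3, semi) {
  q1 <- o[1] / semi[1]; q2 <- o[2] / semi[2]; q3 <- o[3] / semi[3]
  e1 <- d1 / semi[1]; e2 <- d2 / semi[2]; e3 <- d3 / semi[3]
  A <- e1^2 + e2^2 + e3^2
  B <- 2 * (q1 * e1 + q2 * e2 + q3 * e3)
  C <- q1^2 + q2^2 + q3^2 - 1
  disc <- B^2 - 4 * A * C
  t <- (-B - sqrt(pmax(disc, 0))) / (2 * A)
  ifelse(disc >= 0 & t > 0, t, Inf)
}

.check_in_frame <- function(scene, script, subj, pose, pivot, e_up, e_f, e_l,
                            phi, i) {
  top <- pose$kappa * subj$torso_top
  hc <- pose$kappa * subj$head_center
  corners <- as.matrix(expand.grid(l = c(-1, 1) * subj$torso_w / 2,
                                   f = c(-1, 1) * subj$torso_th / 2,
                                   u = c(0, top)))
  extremes <- rbind(corners,
                    cbind(c(-1, 1, 0, 0, 0, 0) * subj$head_r,
                          c(0, 0, -1, 1, 0, 0) * subj$head_r,
                          hc + c(0, 0, 0, 0, -1, 1) * subj$head_rv))
  pw <- t(apply(extremes, 1, function(b)
    pivot + b[1] * e_l + b[2] * e_f + b[3] * e_up))
  pc <- .world_to_cam(pw, phi)
  if (any(pc[, 3] <= 0)) stop("script error: subject leaves frame (behind camera) at frame ", i - 1L)
  px <- world_to_pixel(scene$cam, pc)
  if (any(px[, 1] < 0 | px[, 1] > scene$width - 1 |
          px[, 2] < 0 | px[, 2] > scene$height - 1))
    stop("script error: subject leaves frame at frame ", i - 1L)
  invisible(TRUE)
}

#' A floor region-of-interest known to lie on the synthetic floor
#'
#' Returns a rectangular pixel polygon in the lower part of the image whose
#' pixels are all true floor in the clean background geometry, for use as the
#' user-designated "definite floor area".
#'
#' @param scene a [scene_config()].
#' @return 4x2 matrix of (u, v) vertices.
#' @export
scene_floor_roi <- function(scene) {
  geo <- .bg_geometry(scene)
  w <- scene$width; h <- scene$height
  u0 <- round(0.3 * w); u1 <- round(0.7 * w)
  v1 <- h - 5L
  v0 <- round(0.8 * h)
  while (v0 > 1L && !all(geo$floor[(v0:v1) + 1L, (u0:u1) + 1L])) v0 <- v0 + 5L
  if (!all(geo$floor[(v0:v1) + 1L, (u0:u1) + 1L]))
    stop("no all-floor rectangle found; adjust the scene")
  cbind(u = c(u0, u1, u1, u0), v = c(v0, v0, v1, v1))
}

#' Generate the standard benchmark fixture set
#'
#' Emits the fixture the pipeline is validated on: one block of background
#' frames plus one fall sequence per orientation (anterior, posterior, left,
#' right) and walk/sit control sequences, each with analytic ground truth.
#' Regeneration with the same seed is bit-identical.
#'
#' @param seed integer seed.
#' @param n_background background-only frames (default 40).
#' @param n_frames frames per activity sequence (default 150).
#' @param scene optional [scene_config()]; its seed is re-derived from `seed`.
#' @return list with `scene`, `roi`, `background` (from
#'   [render_background()]) and `sequences` (named list of
#'   [render_activity()] results).
#' @export
make_benchmark <- function(seed = 1L, n_background = 40L, n_frames = 150L,
                           scene = NULL) {
  base <- as.integer(abs(seed) %% 100000L)
  if (is.null(scene)) scene <- scene_config(seed = base)
  specs <- list(
    anterior = list(activity = "fall", orientation = "anterior"),
    posterior = list(activity = "fall", orientation = "posterior"),
    left = list(activity = "fall", orientation = "left"),
    right = list(activity = "fall", orientation = "right"),
    walk = list(activity = "walk", orientation = "anterior"),
    sit = list(activity = "sit", orientation = "anterior"))
  scene$seed <- base
  bg <- render_background(scene, n_background)
  sequences <- lapply(seq_along(specs), function(k) {
    sc <- scene
    sc$seed <- base + 101L * k
    sp <- specs[[k]]
    render_activity(sc, activity_script(activity = sp$activity,
                                        orientation = sp$orientation,
                                        n_frames = n_frames))
  })
  names(sequences) <- names(specs)
  list(scene = scene, roi = scene_floor_roi(scene), background = bg,
       sequences = sequences)
}
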