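#' Run the full fall-detection pipeline on a depth sequence
#'
#' Orchestrates every stage: background fitting (unless a pre-fitted model is
#' supplied), floor-plane extraction from the configured ROI, then per frame:
#' silhouette extraction and background update, silhouette cleaning, head
#' localization on the first frame with a subject, STC tracking on every
#' following frame, head height against the floor plane, and the adaptive
#' two-stage fall decision. The centroid height (second judgment) is computed
#' lazily — only on frames whose head height falls below the threshold.
#'
#' @param frames list of depth frames (a `depth_sequence` works).
#' @param config partial configuration list merged over [default_config()];
#'   `config$floor$roi_polygon` is required unless `floor` is supplied.
#' @param background optional pre-fitted `gauss_background`. When absent, the
#'   first `config$background$n_fit` frames are used to fit it and processing
#'   starts after them.
#' @param floor optional pre-computed `floor_plane`.
#' @return A `fall_result`: list with `events` (list of `fall_event`),
#'   `trajectory` (tibble: frame, u, v, head_h_mm, centroid_h_mm,
#'   confidence, status), `state` (`fall_state`), `head` (first detection),
#'   `background`, `plane`, `n_centroid_evals`, `n_below_threshold`.
#' @export
run_pipeline <- function(frames, config = NULL, background = NULL, floor = NULL) {
  cfg <- merge_config(config)
  cam <- .cam_from_config(cfg)
  bgc <- cfg$background

  if (is.null(background)) {
    if (length(frames) <= bgc$n_fit)
      stop(sprintf("sequence has %d frames but %d background frames are required",
                   length(frames), bgc$n_fit))
    background <- fit_background(frames[seq_len(bgc$n_fit)],
                                 sigma_min = bgc$sigma_min_mm,
                                 alpha = bgc$alpha, beta = bgc$beta)
    frames <- frames[-seq_len(bgc$n_fit)]
  } else {
    background$alpha <- bgc$alpha
    background$beta <- bgc$beta
  }

  if (is.null(floor)) {
    if (is.null(cfg$floor$roi_polygon))
      stop("config$floor$roi_polygon is required when no floor plane is supplied")
    fl <- extract_floor(background, cfg$floor$roi_polygon, cam,
                        inlier_tol = cfg$floor$inlier_tol)
    plane <- fl$plane
    floor_mask <- fl$mask
  } else {
    plane <- floor
    floor_mask <- NULL
  }

  state <- fall_state(debounce = cfg$fall$debounce)
  tracker <- NULL
  head0 <- NULL
  bbox_du <- bbox_dv <- NULL
  n_centroid_evals <- 0L
  n_below <- 0L
  rows <- vector("list", length(frames))

  for (i in seq_along(frames)) {
    f <- frames[[i]]
    fidx <- attr(f, "index")
    if (is.null(fidx)) fidx <- i - 1L
    sil <- extract_silhouette(background, f)
    background <- update_background(background, f, sil)
    cln <- clean_mask(sil, min_area = bgc$min_area_px)

    if (is.null(tracker)) {
      if (!any(cln)) {
        rows[[i]] <- list(frame = fidx, u = NA_real_, v = NA_real_,
                          head_h_mm = NA_real_, centroid_h_mm = NA_real_,
                          confidence = NA_real_, status = "no-subject")
        next
      }
      head0 <- tryCatch(
        locate_head(cln, radius_range = c(cfg$head$radius_min_px,
                                          cfg$head$radius_max_px),
                    n_segments = cfg$head$n_segments,
                    min_score = cfg$head$min_score),
        error = function(e) stop("first subject frame (", fidx,
                                 "): ", conditionMessage(e)))
      center <- head0$ellipse$center
      bbox <- head0$bbox
      bbox_du <- (bbox[["u1"]] - bbox[["u0"]]) / 2
      bbox_dv <- (bbox[["v1"]] - bbox[["v0"]]) / 2
      tkc <- cfg$tracker
      tracker <- stc_init(f, center, bbox_side = 2 * max(bbox_du, bbox_dv),
                          context_scale = tkc$context_scale, rho = tkc$rho,
                          lam = tkc$lam, alpha_c = tkc$alpha_c,
                          beta_c = tkc$beta_c,
                          sigma_w_scale = tkc$sigma_w_scale)
      conf_max <- NA_real_
    } else {
      ts <- track_step(tracker, f)
      tracker <- ts$model
      center <- ts$center
      conf_max <- max(ts$confidence)
      if (conf_max < cfg$tracker$conf_floor)
        warning(sprintf("frame %d: confidence %.3g below floor; possible tracking divergence",
                        fidx, conf_max))
    }

    bbox_now <- c(center[[1]] - bbox_du, center[[2]] - bbox_dv,
                  center[[1]] + bbox_du, center[[2]] + bbox_dv)
    hh <- tryCatch(
      head_height(plane, cam, center, f, bbox_now, mask = cln),
      error = function(e) NULL)
    if (is.null(hh)) {
      warning(sprintf("frame %d: head depth unavailable, frame skipped", fidx))
      rows[[i]] <- list(frame = fidx, u = center[[1]], v = center[[2]],
                        head_h_mm = NA_real_, centroid_h_mm = NA_real_,
                        confidence = conf_max, status = state$status)
      next
    }

    cent_h_rec <- NA_real_
    if (state$status != "fall") {
      provider <- local({
        frame_l <- f; cln_l <- cln
        function() {
          n_centroid_evals <<- n_centroid_evals + 1L
          if (!any(cln_l)) return(NA_real_)
          cen <- compute_centroid(cln_l)
          d <- tryCatch(representative_depth(frame_l, cln_l),
                        error = function(e) NA_real_)
          if (!is.finite(d)) return(NA_real_)
          point_height(plane, pixel_to_world(cam, cen[["u"]], cen[["v"]], d))
        }
      })
      if (!is.na(state$threshold) && hh$height < state$threshold)
        n_below <- n_below + 1L
      state <- fall_step(state, fidx, hh$height, provider)
      cent_h_rec <- state$h_centroid_series[length(state$h_centroid_series)]
    }
    rows[[i]] <- list(frame = fidx, u = center[[1]], v = center[[2]],
                      head_h_mm = hh$height, centroid_h_mm = cent_h_rec,
                      confidence = conf_max, status = state$status)
  }

  trajectory <- tibble::as_tibble(do.call(rbind.data.frame, rows))
  structure(list(events = state$events, trajectory = trajectory, state = state,
                 head = head0, background = background, plane = plane,
                 floor_mask = floor_mask,
                 n_centroid_evals = n_centroid_evals,
                 n_below_threshold = n_below),
            class = "fall_result")
}

#' @export
print.fall_result <- function(x, ...) {
  cat(sprintf("<fall_result> %d frame(s), status %s, %d fall event(s)\n",
              nrow(x$trajectory), x$state$status, length(x$events)))
  if (length(x$events)) for (e in x$events) print(e)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `trajectory.csv` (frame, u, v, head_h_mm, centroid_h_mm, confidence,
#' status), `events.json`, and `plane.json` with the floor coefficients.
#'
#' @param result a `fall_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$trajectory, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  ev <- lapply(result$events, function(e)
    list(frame = e$frame, head_height_mm = e$head_height,
         centroid_height_mm = e$centroid_height, threshold_mm = e$threshold))
  jsonlite::write_json(ev, file.path(dir, "events.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(A = result$plane$A, B = result$plane$B,
                            C = result$plane$C),
                       file.path(dir, "plane.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
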