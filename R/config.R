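#' Default pipeline configuration
#'
#' Nested list of every tunable parameter, organised by stage. All values can
#' be overridden via [read_config()] or by passing a partial list to
#' [run_pipeline()] (missing entries fall back to these defaults).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    camera = list(fx = 285.6, fy = 285.6, cx = 159.5, cy = 119.5,
                  max_range_mm = 10000),
    background = list(n_fit = 40L, alpha = 0.05, beta = 0.05,
                      sigma_min_mm = 10, min_area_px = 200L),
    head = list(n_segments = 40L, radius_min_px = 5, radius_max_px = 14,
                min_score = 0.4),
    tracker = list(context_scale = 4, rho = 0.075, lam = 1e-3,
                   alpha_c = 2.25, beta_c = 1, sigma_w_scale = 0.5,
                   conf_floor = 1e-6),
    floor = list(roi_polygon = NULL, inlier_tol = 0.05),
    fall = list(debounce = 1L)
  )
}

#' Read a YAML configuration file
#'
#' Reads the pipeline configuration and merges it over [default_config()]
#' recursively, so a file may specify only the parameters it changes.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

#' Merge a partial configuration over the defaults
#'
#' @param config partial nested list (may be `NULL`).
#' @return complete configuration list.
#' @export
merge_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  for (blk in names(config)) {
    if (blk %in% names(base) && is.list(config[[blk]])) {
      base[[blk]] <- utils::modifyList(base[[blk]], config[[blk]])
    } else {
      base[[blk]] <- config[[blk]]
    }
  }
  base
}

.cam_from_config <- function(config) {
  cc <- config$camera
  camera_model(cc$fx, cc$fy, cc$cx, cc$cy, cc$max_range_mm)
}
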