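#' Plot head and centroid height trajectories
#'
#' Heights above the floor over time, with the adaptive threshold
#' (0.25 of the first head height) and any fall event marked.
#'
#' @param x a `fall_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_heights <- function(x, ...) {
  tr <- x$trajectory
  df <- rbind(
    data.frame(frame = tr$frame, height = tr$head_h_mm, series = "head"),
    data.frame(frame = tr$frame, height = tr$centroid_h_mm, series = "centroid"))
  df <- df[is.finite(df$height), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$height,
                                        colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "frame", y = "height above floor [mm]", colour = NULL) +
    ggplot2::theme_minimal()
  if (is.finite(x$state$threshold))
    p <- p + ggplot2::geom_hline(yintercept = x$state$threshold,
                                 linetype = "dashed")
  for (e in x$events)
    p <- p + ggplot2::geom_vline(xintercept = e$frame, colour = "red",
                                 linetype = "dotted")
  p
}

#' @rdname plot_heights
#' @param object a `fall_result`.
#' @export
autoplot.fall_result <- function(object, ...) plot_heights(object, ...)

#' Plot a depth frame or mask as an image
#'
#' @param m matrix (depth in mm or logical mask).
#' @param main plot title.
#' @return invisibly, `m`.
#' @export
plot_depth <- function(m, main = NULL) {
  m <- unclass(m)
  storage.mode(m) <- "numeric"
  graphics::image(t(m)[, nrow(m):1], col = grDevices::hcl.colors(64, "viridis"),
                  asp = nrow(m) / ncol(m), axes = FALSE, main = main)
  invisible(m)
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
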