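# Dense spatio-temporal context (STC) tracking on the depth channel.
#
# The tracker learns, in the frequency domain, a spatial-context filter h^sc
# relating the target position to the depth values of its surrounding context
# window; the confidence map of the next frame is the circular convolution of
# h^sc with the new context prior and its argmax is the new target position.
# The filter is blended over time with rate rho.

# extract an n x n window centred at (u, v) (0-based), replication-padded
.window <- function(frame, center, n) {
  m <- unclass(frame)
  half <- (n - 1L) %/% 2L
  rows <- pmin(pmax(round(center[[2]]) - half + 0:(n - 1L), 0L), nrow(m) - 1L) + 1L
  cols <- pmin(pmax(round(center[[1]]) - half + 0:(n - 1L), 0L), ncol(m) - 1L) + 1L
  m[rows, cols, drop = FALSE]
}

# zero-mean / unit-deviation normalization over valid pixels; invalid -> 0
.norm_window <- function(w) {
  ok <- w > 0
  if (!any(ok)) return(matrix(0, nrow(w), ncol(w)))
  mu <- mean(w[ok])
  s <- stats::sd(w[ok])
  if (!is.finite(s) || s < 1e-9) s <- 1
  out <- (w - mu) / s
  out[!ok] <- 0
  out
}

# squared distance from the window centre, n x n
.radius2 <- function(n) {
  half <- (n - 1) / 2
  d <- (0:(n - 1)) - half
  outer(d^2, d^2, `+`)
}

#' Gaussian context weight
#'
#' Distance weight `exp(-r^2 / (2 sigma_w^2))` over an odd window, normalized
#' to sum to 1.
#'
#' @param context_size odd window side in pixels.
#' @param sigma_w Gaussian scale in pixels.
#' @return numeric `context_size x context_size` matrix summing to 1.
#' @export
context_weight <- function(context_size, sigma_w) {
  stopifnot(context_size %% 2L == 1L, sigma_w > 0)
  w <- exp(-.radius2(context_size) / (2 * sigma_w^2))
  w / sum(w)
}

#' Context prior of a depth window
#'
#' The prior is the normalized depth intensity of the context window times a
#' Gaussian distance weight centred on the previous target position (weight
#' normalized to sum 1 over the window). Depth is normalized per window to
#' zero mean and unit deviation over valid pixels so the spectral division in
#' the learning step is well conditioned; invalid pixels contribute 0.
#'
#' @param frame a depth frame.
#' @param center `c(u, v)` previous target position (0-based pixels).
#' @param context_size odd window side in pixels.
#' @param sigma_w Gaussian weight scale in pixels.
#' @return numeric `context_size x context_size` matrix.
#' @export
context_prior <- function(frame, center, context_size, sigma_w) {
  .norm_window(.window(frame, center, context_size)) *
    context_weight(context_size, sigma_w)
}

#' Target confidence map
#'
#' The confidence the learner is trained to reproduce:
#' `c(x) = exp(-(|x - centre| / alpha_c)^beta_c)`, peaked at 1 in the window
#' centre and decaying with a slightly heavier-than-Gaussian tail for
#' `beta_c = 1`, which biases learning toward the target over its context.
#'
#' @param context_size odd window side in pixels.
#' @param alpha_c scale parameter (pixels).
#' @param beta_c shape parameter.
#' @return numeric `context_size x context_size` matrix with 1 at the centre.
#' @export
target_confidence <- function(context_size, alpha_c = 2.25, beta_c = 1) {
  stopifnot(context_size %% 2L == 1L)
  r <- sqrt(.radius2(context_size))
  exp(-(r / alpha_c)^beta_c)
}

#' Learn the spatial-context filter on one frame
#'
#' Solves `c = h^sc (*) (I w_sigma)` (circular convolution) for `h^sc` by
#' conjugate-regularized spectral division:
#' `Hsc = F(c) Conj(F(P)) / (|F(P)|^2 + lam)` with `P = I w_sigma`.
#' As `lam -> 0` this is the exact deconvolution `F(c)/F(P)`; the conjugate
#' form keeps the denominator real and positive, so frequencies where the
#' context spectrum vanishes (smooth depth scenes) degrade gracefully to a
#' matched-filter response instead of amplifying noise.
#'
#' @param frame a depth frame.
#' @param center `c(u, v)` target position.
#' @param model an [stc_init()] model (supplies window size and parameters).
#' @return complex matrix: the filter in the frequency domain.
#' @export
learn_spatial_context <- function(frame, center, model) {
  p <- context_prior(frame, center, model$context_size, model$sigma_w)
  cm <- target_confidence(model$context_size, model$alpha_c, model$beta_c)
  Fp <- stats::fft(p)
  stats::fft(cm) * Conj(Fp) / (Mod(Fp)^2 + model$lam)
}

#' Blend the spatial filter over time
#'
#' `Hsc <- (1 - rho) Hsc + rho Hsc_new`; the temporal half of the
#' spatio-temporal context model.
#'
#' @param model an STC model.
#' @param Hsc_new newly learned frequency-domain filter.
#' @return the model with the blended filter.
#' @export
update_temporal <- function(model, Hsc_new) {
  if (!all(dim(model$Hsc) == dim(Hsc_new))) stop("filter grid mismatch")
  model$Hsc <- (1 - model$rho) * model$Hsc + model$rho * Hsc_new
  model
}

#' Initialize an STC tracker on a detected target
#'
#' The context window side defaults to `context_scale` times the target
#' bounding-box side (rounded up to odd) and the Gaussian weight scale to
#' `sigma_w_scale` times the semi-axis `b`; the tracking scale is frozen at
#' initialization. The spatial filter is learned immediately on `frame`.
#'
#' @param frame the frame the target was detected in.
#' @param center `c(u, v)` target position (0-based pixels).
#' @param bbox_side target bounding-box side in pixels.
#' @param context_scale window side as a multiple of `bbox_side` (default 4).
#' @param rho temporal learning rate (default 0.075).
#' @param lam spectral-division regularizer (default 1e-3).
#' @param alpha_c,beta_c confidence-target shape (defaults 2.25, 1).
#' @param sigma_w_scale Gaussian weight scale as a multiple of the target
#'   semi-axis (default 0.5); `sigma_w = sigma_w_scale * bbox_side / 2`.
#' @return An `stc_model`.
#' @export
stc_init <- function(frame, center, bbox_side, context_scale = 4, rho = 0.075,
                     lam = 1e-3, alpha_c = 2.25, beta_c = 1,
                     sigma_w_scale = 0.5) {
  n <- round(context_scale * bbox_side)
  n <- min(n, min(dim(frame)) - 1L)
  if (n %% 2L == 0L) n <- n + 1L
  model <- structure(list(center = c(u = center[[1]], v = center[[2]]),
                          context_size = as.integer(n),
                          rho = rho, lam = lam, alpha_c = alpha_c,
                          beta_c = beta_c,
                          sigma_w = max(1, sigma_w_scale * bbox_side / 2),
                          Hsc = NULL),
                     class = "stc_model")
  model$Hsc <- learn_spatial_context(frame, model$center, model)
  model
}

#' Advance the tracker by one frame
#'
#' Computes the confidence map `IFFT(Hsc * F(I w_sigma))` over the context
#' window around the previous centre, moves the centre to its argmax (ties:
#' smallest row, then column), then learns on the new frame at the new centre
#' and blends the filter temporally.
#'
#' @param model an `stc_model`.
#' @param frame the next depth frame.
#' @return list with `model` (updated), `center` (`c(u, v)`), and
#'   `confidence` (the confidence map matrix).
#' @export
track_step <- function(model, frame) {
  n <- model$context_size
  p <- context_prior(frame, model$center, n, model$sigma_w)
  conf <- Re(stats::fft(model$Hsc * stats::fft(p), inverse = TRUE)) / (n * n)
  if (!all(is.finite(conf))) stop("numeric error: non-finite confidence values")
  mx <- max(conf)
  pk <- which(conf >= mx - 1e-12, arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE][1, ]
  half <- (n - 1L) %/% 2L
  new_center <- c(u = round(model$center[["u"]]) + (pk[[2]] - 1L - half),
                  v = round(model$center[["v"]]) + (pk[[1]] - 1L - half))
  new_center["u"] <- min(max(new_center[["u"]], 0), ncol(frame) - 1L)
  new_center["v"] <- min(max(new_center[["v"]], 0), nrow(frame) - 1L)
  model$center <- new_center
  Hsc_new <- learn_spatial_context(frame, new_center, model)
  model <- update_temporal(model, Hsc_new)
  list(model = model, center = new_center, confidence = conf)
}
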