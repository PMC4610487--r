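# Programmatic fixtures shared across test files.

# logical mask with a filled ellipse (pixel-centre inside test), 0-based centre
ellipse_mask <- function(h, w, cu, cv, a, b, scale = 1) {
  uu <- matrix(rep(0:(w - 1), each = h), h, w)
  vv <- matrix(rep(0:(h - 1), times = w), h, w)
  ((uu - cu) / (a * scale))^2 + ((vv - cv) / (b * scale))^2 <= 1
}

disk_mask <- function(h, w, cu, cv, r) ellipse_mask(h, w, cu, cv, r, r)

# standing-figure mask: disk head on a box torso
figure_mask <- function(h = 120, w = 100, head_u = 50, head_v = 20, head_r = 10,
                        torso_w = 36, torso_top = 28, torso_bot = 110) {
  m <- disk_mask(h, w, head_u, head_v, head_r)
  m[(torso_top:torso_bot) + 1, (head_u - torso_w / 2):(head_u + torso_w / 2) + 1] <- TRUE
  m
}

# constant-depth frame with an optional square blob at depth blob_d
blob_frame <- function(h = 120, w = 160, bg_d = 4000, blob = NULL, blob_d = 2000,
                       blob_r = 5, index = 0L) {
  m <- matrix(bg_d, h, w)
  if (!is.null(blob)) {
    mask <- disk_mask(h, w, blob[1], blob[2], blob_r)
    m[mask] <- blob_d
  }
  depth_frame(m, index = index)
}

# gauss background with hand-set parameters (for decision-rule unit tests)
manual_background <- function(h, w, mu, sigma, sigma_min = 10) {
  structure(list(mu = matrix(mu, h, w), sigma = matrix(sigma, h, w),
                 valid = matrix(TRUE, h, w), n_fit = 2L,
                 alpha = 0.05, beta = 0.05, sigma_min = sigma_min),
            class = "gauss_background")
}

# brute-force circular convolution conv(hs, p)[x] = sum_z hs(x - z) p(z)
circ_conv2 <- function(hs, p) {
  n <- nrow(hs)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    rs <- ((i - 1) - (seq_len(n) - 1)) %% n + 1
    cs <- ((j - 1) - (seq_len(n) - 1)) %% n + 1
    out[i, j] <- sum(hs[rs, cs] * p)
  }
  out
}

# small default test scene (full frame size; sequences kept short in tests)
test_scene <- function(seed = 7, ...) scene_config(seed = seed, ...)
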