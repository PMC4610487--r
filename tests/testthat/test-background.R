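test_that("background fitting recovers per-pixel mean and deviation", {
  frames <- lapply(1:40, function(i) depth_frame(matrix(2000L, 8, 8), index = i - 1))
  bg <- fit_background(frames, sigma_min = 10)
  expect_true(all(bg$mu == 2000))
  expect_true(all(bg$sigma == 10))          # zero variance floored at sigma_min

  obs <- c(1000L, 2000L, 3000L)
  frames3 <- lapply(1:3, function(i) depth_frame(matrix(obs[i], 4, 4)))
  bg3 <- fit_background(frames3, sigma_min = 1)
  expect_equal(bg3$mu[1, 1], 2000)
  expect_equal(round(bg3$sigma[1, 1], 2), 816.50)   # sqrt(mean sq deviation)

  obs0 <- c(0L, 2000L, 2000L)               # invalid excluded per pixel
  bg0 <- fit_background(lapply(obs0, function(d) depth_frame(matrix(d, 4, 4))),
                        sigma_min = 5)
  expect_equal(bg0$mu[2, 2], 2000)

  expect_error(fit_background(frames3[1]), "at least 2")
  mostly0 <- lapply(1:3, function(i) {
    m <- matrix(0L, 10, 10); m[1, 1:4] <- 1500L; depth_frame(m)
  })
  expect_warning(fit_background(mostly0), "degenerate background")
})

test_that("silhouette extraction applies the 2.5-sigma rule with background tie-break", {
  bg <- manual_background(6, 6, mu = 2000, sigma = 40)
  f <- depth_frame(matrix(2000L, 6, 6))
  f[2, 2] <- 2101L     # |101| > 100 -> foreground
  f[3, 3] <- 2100L     # boundary -> background
  f[4, 4] <- 0L        # invalid -> background regardless
  sil <- extract_silhouette(bg, f)
  expect_true(sil[2, 2])
  expect_false(sil[3, 3])
  expect_false(sil[4, 4])
  expect_error(extract_silhouette(bg, depth_frame(matrix(2000L, 3, 3))),
               "dimension mismatch")
})

test_that("empirical foreground rate on background-only frames matches the 2.5-sigma tail", {
  # > 1e5 pixels, each N(2000, 20^2); expected rate 2*(1 - pnorm(2.5)) = 1.24%
  set.seed(20)
  h <- 320L; w <- 320L
  n_fit <- 120L
  frames <- lapply(seq_len(n_fit), function(i)
    depth_frame(matrix(as.integer(round(rnorm(h * w, 2000, 20))), h, w)))
  bg <- fit_background(frames, sigma_min = 1)
  probe <- depth_frame(matrix(as.integer(round(rnorm(h * w, 2000, 20))), h, w))
  rate <- mean(extract_silhouette(bg, probe))
  expect_lt(abs(rate - (1 - (pnorm(2.5) - pnorm(-2.5)))), 0.003)
})

test_that("background update blends background pixels and freezes foreground pixels", {
  bg <- manual_background(4, 4, mu = 2000, sigma = 40)
  f <- depth_frame(matrix(2100L, 4, 4))
  mask <- structure(matrix(FALSE, 4, 4), class = c("silhouette_mask", "matrix", "array"))
  mask[1, 1] <- TRUE
  up <- update_background(bg, f, mask)
  expect_equal(up$mu[2, 2], 2005)               # (1-0.05)*2000 + 0.05*2100
  expect_identical(up$mu[1, 1], bg$mu[1, 1])    # foreground untouched
  expect_identical(up$sigma[1, 1], bg$sigma[1, 1])

  # constant F = mu is a fixed point for mu; sigma contracts toward the floor
  bg2 <- manual_background(4, 4, mu = 2000, sigma = 40)
  fconst <- depth_frame(matrix(2000L, 4, 4))
  m0 <- structure(matrix(FALSE, 4, 4), class = c("silhouette_mask", "matrix", "array"))
  for (k in 1:5) bg2 <- update_background(bg2, fconst, m0)
  expect_equal(bg2$mu[3, 3], 2000)
  expect_lt(bg2$sigma[3, 3], 40)
  expect_gte(bg2$sigma[3, 3], bg2$sigma_min)
})

test_that("repeated updates converge geometrically at rate (1 - alpha)", {
  bg <- manual_background(3, 3, mu = 1000, sigma = 20)
  f <- depth_frame(matrix(1400L, 3, 3))
  m0 <- structure(matrix(FALSE, 3, 3), class = c("silhouette_mask", "matrix", "array"))
  k <- 12
  cur <- bg
  for (i in seq_len(k)) cur <- update_background(cur, f, m0)
  expect_equal(cur$mu[1, 1] - 1400, (1 - bg$alpha)^k * (1000 - 1400), tolerance = 1e-12)
  # mu stays within the range of everything observed at the pixel
  expect_gte(cur$mu[1, 1], 1000)
  expect_lte(cur$mu[1, 1], 1400)
})

test_that("mask cleaning keeps only the largest sufficient component and is idempotent", {
  m <- matrix(FALSE, 100, 100)
  m[20:59, 30:69] <- TRUE                         # 40x40 blob
  speck <- cbind(c(5, 90, 8, 95, 3), c(5, 90, 80, 10, 50))
  m[speck] <- TRUE
  msk <- structure(m, index = 0L, class = c("silhouette_mask", "matrix", "array"))
  out <- clean_mask(msk, min_area = 200)
  expect_true(all(out[20:59, 30:69]))              # solid blob preserved
  expect_false(any(out[speck]))
  expect_lte(sum(out), sum(msk))
  expect_identical(unclass(clean_mask(out, min_area = 200)), unclass(out))

  empty <- structure(matrix(FALSE, 10, 10), index = 0L,
                     class = c("silhouette_mask", "matrix", "array"))
  expect_identical(sum(clean_mask(empty)), 0L)

  two <- matrix(FALSE, 80, 80)
  two[2:26, 2:21] <- TRUE                          # 500 px
  two[40:59, 40:59] <- TRUE                        # 400 px
  two <- structure(two, index = 0L, class = c("silhouette_mask", "matrix", "array"))
  kept <- clean_mask(two, min_area = 100)
  expect_true(any(kept[2:26, 2:21]))
  expect_false(any(kept[40:59, 40:59]))
})

test_that("centroid is the binary first moment and translation-equivariant", {
  m <- matrix(FALSE, 10, 10)
  m[4, 3] <- TRUE                                  # pixel (u=2, v=3)
  expect_equal(compute_centroid(m), c(u = 2, v = 3))
  m2 <- matrix(FALSE, 10, 10)
  m2[cbind(c(1, 1, 3, 3), c(1, 3, 1, 3))] <- TRUE
  expect_equal(compute_centroid(m2), c(u = 1, v = 1))
  expect_error(compute_centroid(matrix(FALSE, 5, 5)), "no subject")

  set.seed(8)
  base <- matrix(FALSE, 40, 40)
  base[cbind(sample(10:20, 30, TRUE), sample(10:20, 30, TRUE))] <- TRUE
  c0 <- compute_centroid(base)
  sh <- matrix(FALSE, 40, 40)
  sh[which(base, arr.ind = TRUE) + matrix(c(7, 5), sum(base), 2, byrow = TRUE)] <- TRUE
  expect_equal(compute_centroid(sh), c0 + c(u = 5, v = 7))
})
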