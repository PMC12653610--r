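const_frame <- function(value, H = 40, W = 40) array(value, c(H, W, 3))

test_that("frame averaging is exact and obeys the sqrt(n) noise law", {
  f1 <- const_frame(10); f2 <- const_frame(20); f3 <- const_frame(30)
  expect_identical(average_frames(list(f1)), f1)
  expect_equal(average_frames(list(f1, f2, f3)), const_frame(20))
  expect_error(average_frames(list(f1, const_frame(1, H = 10))), "mismatch")
  # Monte-Carlo over pixels: residual noise SD of a 3-frame mean ~ sigma/sqrt(3)
  set.seed(5)
  sigma <- 4
  frames <- lapply(1:3, function(i) {
    const_frame(100, 80, 80) + array(rnorm(80 * 80 * 3, 0, sigma), c(80, 80, 3))
  })
  avg <- average_frames(frames)
  expect_equal(sd(as.vector(avg)), sigma / sqrt(3), tolerance = 0.1)
})

test_that("flat-field correction cancels a shared vignetting field", {
  H <- 60; W <- 60
  dark <- const_frame(0, H, W)
  white <- const_frame(200, H, W)
  # raw == white, dark == 0 -> constant at the white spatial mean
  out <- flat_field_correct(white, dark, white)
  expect_equal(as.vector(out), rep(200, H * W * 3), tolerance = 1e-9)
  # multiplicative field identical in raw and white -> corrected CV ~ 0
  field <- outer(seq(0.8, 1.2, length.out = H), seq(0.9, 1.1, length.out = W))
  raw <- white
  for (ch in 1:3) { raw[, , ch] <- 150 * field; white[, , ch] <- 200 * field }
  out <- flat_field_correct(raw, dark, white)
  lum <- luminance(out)
  expect_lt(sd(lum) / mean(lum), 1e-9)
  expect_equal(mean(out[, , 1]), 150 / 200 * mean(200 * field), tolerance = 1e-6)
})

test_that("flat-field correction reduces the imposed ~12.3% spatial CV below 2.8%", {
  sc <- make_scene(scene_config(grade = "white_crepe", seed = 31))
  fs <- sc$frameset
  raw <- average_frames(fs$frames)
  pre_cv <- sd(luminance(fs$white)) / mean(luminance(fs$white))
  expect_equal(pre_cv, 0.123, tolerance = 0.01)
  corr <- flat_field_correct(raw, fs$dark, fs$white)
  lum <- luminance(corr)[sc$truth_mask]
  expect_lte(sd(lum) / mean(lum), 0.028)
})

test_that("flat-field correction masks degenerate pixels instead of emitting NaN", {
  H <- 10; W <- 10
  dark <- const_frame(5, H, W)
  white <- const_frame(5, H, W)   # white == dark everywhere: all degenerate
  white[1, 1, ] <- 200
  raw <- const_frame(100, H, W)
  expect_error(raw_frame_set(list(raw), dark, dark), "brighter")
  out <- flat_field_correct(raw, dark, white)
  expect_false(any(!is.finite(out)))
  excl <- excluded_mask(out)
  expect_true(all(excl[2, 2, ]))
  expect_false(any(excl[1, 1, ]))
})

test_that("flat-field correction is idempotent under a constant white reference", {
  H <- 30; W <- 30
  raw <- const_frame(120, H, W) + array(runif(H * W * 3, -5, 5), c(H, W, 3))
  dark <- const_frame(0, H, W)
  white <- const_frame(180, H, W)
  once <- flat_field_correct(raw, dark, white)
  twice <- flat_field_correct(once, dark, white)
  expect_equal(as.vector(twice), as.vector(once), tolerance = 1e-12)
})

test_that("Gaussian denoising preserves constants, mass, and shape", {
  img <- const_frame(42, 30, 30)
  out <- gaussian_denoise(img, 1.2)
  expect_equal(dim(out), dim(img))
  expect_equal(as.vector(out), as.vector(img), tolerance = 1e-9)
  # unit impulse reproduces the normalized kernel
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  sm <- gaussian_denoise(imp, 1.2)
  k <- gauss_kernel(1.2)
  r <- (nrow(k) - 1) / 2
  expect_equal(sm[16 + (-r:r), 16 + (-r:r)], k, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("denoising variance reduction matches the kernel-weights oracle", {
  set.seed(9)
  img <- matrix(rnorm(200 * 200), 200, 200)
  sm <- gaussian_denoise(img, 1.2)
  factor <- var(as.vector(sm[20:180, 20:180])) / var(as.vector(img))
  expect_equal(factor, sum(gauss_kernel(1.2)^2), tolerance = 0.05)
})

test_that("quality metrics implement the SNR closed form and the gates", {
  H <- 80; W <- 80
  set.seed(13)
  # dark frame with unit noise SD around 0 -> mu_signal 100 / sigma 1 = 40 dB
  dark <- array(rnorm(H * W * 3, 50, 1.3), c(H, W, 3))
  white <- const_frame(100, H, W)   # luminance weights sum to 1
  frames <- list(const_frame(80, H, W))
  fs <- raw_frame_set(frames, dark, white, pixel_pitch_mm = 0.25)
  qm <- compute_quality(fs)
  sigma <- sd(luminance(dark))
  expect_equal(qm$snr_db, 20 * log10(100 / sigma), tolerance = 1e-6)
  expect_equal(qm$uniformity_cv, 0, tolerance = 1e-12)
  expect_true(qm$pass_flags$uniformity)
  expect_true(qm$pass_flags$saturation)
})

test_that("white reference with 3% multiplicative CV passes the uniformity gate", {
  H <- 140; W <- 140
  set.seed(17)
  field <- matrix(rnorm(H * W, 1, 0.03), H, W)
  white <- array(rep(180 * field, 3), c(H, W, 3))
  fs <- raw_frame_set(list(array(120, c(H, W, 3))),
                      dark = array(rnorm(H * W * 3, 2, 0.5), c(H, W, 3)),
                      white = white, pixel_pitch_mm = 0.5)
  qm <- compute_quality(fs)
  expect_equal(qm$uniformity_cv, 0.03, tolerance = 0.003)
  expect_true(qm$pass_flags$uniformity)
})

test_that("saturated frames trip the saturation gate", {
  H <- 100; W <- 100
  img <- array(150, c(H, W, 3))
  img[1:10, 1:10, ] <- 255          # exactly 1% of pixels clipped
  fs <- raw_frame_set(list(img), dark = array(rnorm(H * W * 3, 1, 0.4), c(H, W, 3)),
                      white = array(200, c(H, W, 3)))
  qm <- compute_quality(fs)
  expect_equal(qm$saturation_fraction, 0.01)
  expect_false(qm$pass_flags$saturation)
  expect_false(qm$pass_flags$all)
})

test_that("focus gate separates sharp from defocused content", {
  sc <- make_scene(scene_config(seed = 3))
  qm <- compute_quality(sc$frameset)
  expect_gt(qm$focus_score, 0.7)
  blur <- lapply(sc$frameset$frames, gaussian_denoise, sigma = 6)
  fs2 <- raw_frame_set(blur, sc$frameset$dark, sc$frameset$white)
  expect_lt(compute_quality(fs2)$focus_score, 0.7)
})

test_that("exposure classification follows the 60-80% dynamic-range window", {
  ok <- array(0.70 * 255, c(20, 20, 3))
  expect_identical(check_exposure(ok), "ok")
  expect_identical(check_exposure(array(0, c(20, 20, 3))), "too_low")
  expect_identical(check_exposure(array(255, c(20, 20, 3))), "too_high")
})
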