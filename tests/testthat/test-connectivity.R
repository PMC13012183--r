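# Preprocessing chain (downsample, detrend, bandpass, GSR), mirror
# geometry, homotopic correlation maps and the connectivity index.

test_that("block-mean downsampling preserves per-frame spatial means", {
  set.seed(1)
  fr <- array(runif(2 * 16 * 16, 0, 255), c(2, 16, 16))
  st <- image_stack(fr, frame_rate_hz = 3)
  ds <- downsample_movie(st, c(4, 4))
  expect_equal(dim(ds$frames), c(2, 4, 4))
  for (f in 1:2) {
    expect_equal(mean(ds$frames[f, , ]), mean(fr[f, , ]), tolerance = 1e-12)
  }
  # checkerboard block of {0, 255} averages to 127.5
  cb <- matrix(c(0, 255), 4, 4)
  st2 <- image_stack(cb)
  expect_equal(downsample_movie(st2, c(1, 1))$frames[1, 1, 1], 127.5)
  expect_error(downsample_movie(st, c(5, 5)), class = "mesowin_param_error")
})

test_that("detrending removes ramps and leaves zero-mean residuals", {
  n <- 120
  t <- seq_len(n)
  ramp <- array(0, c(n, 4, 4))
  for (p in 1:16) ramp[, (p - 1) %% 4 + 1, (p - 1) %/% 4 + 1] <- 3 + 0.2 * p * t
  st <- image_stack(ramp, frame_rate_hz = 3)
  res <- detrend_movie(st)
  expect_lt(max(abs(res$frames)), 1e-8)

  sine <- sin(2 * pi * 0.05 * t / 3)
  mixed <- array(rep(5 + 0.1 * t + sine, 16), c(n, 4, 4))
  out <- detrend_movie(image_stack(mixed, frame_rate_hz = 3))
  # sinusoid recovered up to its own tiny linear component
  expect_lt(max(abs(out$frames[, 1, 1] - (sine - mean(sine) -
    stats::lm.fit(cbind(1, t), sine)$coefficients[2] * (t - mean(t))))), 1e-6)
  M <- matrix(out$frames, n)
  expect_lt(max(abs(colMeans(M))), 1e-9)
})

test_that("bandpass keeps in-band and rejects out-of-band sinusoids", {
  n <- 1800
  fs <- 3
  t <- seq_len(n) / fs
  mk <- function(f) image_stack(array(rep(128 + sin(2 * pi * f * t), 4),
                                      c(n, 2, 2)), frame_rate_hz = fs)
  inband <- bandpass_movie(mk(0.055))
  mid <- 450:1350
  expect_gte(max(inband$frames[mid, 1, 1]), 0.9)
  outband <- bandpass_movie(mk(0.5))
  expect_lte(max(abs(outband$frames[mid, 1, 1])), 0.1)
  # DC is removed
  dc <- bandpass_movie(image_stack(array(128, c(600, 2, 2)), frame_rate_hz = fs))
  expect_lt(max(abs(dc$frames)), 1e-9)
  expect_error(bandpass_movie(mk(0.05), low = 0.5, high = 2),
               class = "mesowin_param_error")
})

test_that("GSR residuals are orthogonal to the global regressor", {
  set.seed(2)
  n <- 300
  g <- cumsum(rnorm(n))
  fr <- array(rep(g, 9), c(n, 3, 3)) + array(rnorm(n * 9), c(n, 3, 3))
  st <- image_stack(fr - min(fr), frame_rate_hz = 3)
  res <- global_signal_regression(st)
  gm <- rowMeans(matrix(st$frames, n))
  M <- matrix(res$frames, n)
  for (j in 1:9) expect_lt(abs(cor(M[, j], gm)), 1e-10)
  # a movie that IS the global signal regresses to ~0
  pure <- image_stack(array(rep(g - min(g), 4), c(n, 2, 2)), frame_rate_hz = 3)
  expect_lt(max(abs(global_signal_regression(pure)$frames)), 1e-8)
  expect_error(global_signal_regression(
    image_stack(array(5, c(10, 2, 2)))), class = "mesowin_degenerate_error")
})

test_that("mirror reflection is an involution with the expected fixed points", {
  ml <- midline_axis(c(1, 64), c(100, 64))       # vertical line col = 64
  expect_equal(mirror_pixel(c(10, 60), ml), c(10, 68))
  expect_equal(mirror_pixel(c(33, 64), ml), c(33, 64))  # on the line
  ml2 <- midline_axis(c(3, 10), c(90, 55))       # oblique midline
  set.seed(3)
  for (i in 1:20) {
    p <- c(sample.int(100, 1), sample.int(100, 1))
    q <- mirror_pixel(p, ml2)
    back <- mirror_pixel(q, ml2)
    expect_lte(max(abs(back - p)), 1)            # 1 px rounding
  }
  expect_equal(mirror_pixel(c(1, 1), ml, dm = c(40, 40)), c(NA_real_, NA_real_))
})

test_that("a mirrored-copy movie correlates at the clip ceiling", {
  set.seed(4)
  n <- 60
  left <- array(runif(n * 8 * 4), c(n, 8, 4))
  fr <- array(0, c(n, 8, 8))
  fr[, , 1:4] <- left
  fr[, , 8:5] <- left                            # exact mirror about col 4.5
  st <- image_stack(fr, frame_rate_hz = 3)
  ml <- midline_axis(c(1, 4.5), c(8, 4.5))
  map <- homotopic_map(st, ml)
  expect_true(all(map$paired_mask))
  expect_equal(unname(map$z_map[map$paired_mask]),
               rep(atanh(1 - 1e-7), 64), tolerance = 1e-9)
})

test_that("independent hemispheres give a near-zero index", {
  set.seed(5)
  n <- 1800
  fr <- array(runif(n * 16 * 16, 0, 255), c(n, 16, 16))
  st <- image_stack(fr, frame_rate_hz = 3)
  ml <- midline_axis(c(1, 8.5), c(16, 8.5))
  idx <- connectivity_index(homotopic_map(st, ml))
  expect_lt(abs(idx$value), 3 / sqrt(n - 3))
})

test_that("zero-variance pixels are excluded from pairing, not errors", {
  set.seed(6)
  fr <- array(runif(50 * 6 * 6, 0, 1), c(50, 6, 6))
  fr[, 2, 2] <- 0.7                              # constant pixel
  st <- image_stack(fr, frame_rate_hz = 3)
  ml <- midline_axis(c(1, 3.5), c(6, 3.5))
  map <- homotopic_map(st, ml)
  expect_false(map$paired_mask[2, 2])
  expect_false(map$paired_mask[2, 5])            # its partner drops too
  expect_true(map$paired_mask[3, 3])
})

test_that("the index is the plain mean of paired z values", {
  z <- matrix(NA_real_, 4, 4)
  paired <- matrix(FALSE, 4, 4)
  z[1, 1] <- 0.2; z[1, 4] <- 0.2
  z[2, 1] <- 0.8; z[2, 4] <- 0.8
  paired[1, c(1, 4)] <- TRUE
  paired[2, c(1, 4)] <- TRUE
  map <- structure(list(r_map = tanh(z), z_map = z, paired_mask = paired),
                   class = "connectivity_map")
  idx <- connectivity_index(map, "b")
  expect_equal(idx$value, 0.5)
  expect_equal(idx$n_pixels, 4)
  map$paired_mask[] <- FALSE
  expect_error(connectivity_index(map), class = "mesowin_degenerate_error")
})

test_that("clean bilateral movies recover atanh(rho)", {
  g <- gen_bilateral_movie(clean_bilateral(0.6, seed = 31))
  idx <- connectivity_index(homotopic_map(g$movie, g$truth$midline))
  expect_lt(abs(idx$value - atanh(0.6)), 0.1)
})

test_that("full preprocessing removes drift and global nuisance bias", {
  p <- bilateral_sim_params(shape = c(32, 32), n_frames = 1800, rho = 0.6,
                            drift_slope = 0.02, global_amp = 5, noise_sd = 3,
                            seed = 32)
  g <- gen_bilateral_movie(p)
  pre <- connectivity_preprocess(g$movie)
  idx <- connectivity_index(homotopic_map(pre, g$truth$midline))
  expect_lt(abs(idx$value - atanh(0.6)), 0.15)
  # skipping detrend + GSR leaves the nuisance-inflated correlation
  raw_idx <- connectivity_index(homotopic_map(g$movie, g$truth$midline))
  expect_gt(raw_idx$value - atanh(0.6), 0.15)
})

test_that("frame bookkeeping matches the block design arithmetic", {
  bk <- block_bookkeeping(32.7)
  expect_equal(bk$total_frames, 5886)
  expect_equal(round(bk$discard_minutes, 1), 2.8)
  expect_equal(bk$frames_available, 5386)
  expect_true(bk$last_block_short)
  expect_equal(bk$last_block_frames, 5386 - 2 * 1800)
})
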