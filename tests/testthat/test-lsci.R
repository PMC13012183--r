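# Speckle contrast K, the 1/K^2 flow index, stack averaging, rBF traces
# and occlusion quantification.

test_that("constant images have zero contrast on all valid pixels", {
  st <- image_stack(array(100, c(2, 16, 16)), bit_depth = 8)
  K <- compute_speckle_contrast(st)
  expect_true(all(K$K[K$valid_mask] == 0))
  # border of half-window width is invalid, never silently zero
  expect_true(all(is.na(K$K[1:3, ])))
  expect_equal(sum(K$valid_mask), 10 * 10)
})

test_that("K at a pixel equals sd/mean over its 7x7 window", {
  set.seed(1)
  patch <- matrix(sample.int(256, 49) - 1, 7, 7)
  K <- compute_speckle_contrast(image_stack(patch, bit_depth = 8))
  expect_equal(K$K[4, 4], sd(patch) / mean(patch), tolerance = 1e-12)
  expect_equal(sum(K$valid_mask), 1)
})

test_that("windowed K matches the brute-force double-loop oracle", {
  set.seed(2)
  for (i in 1:5) {
    img <- matrix(runif(32 * 32, 10, 250), 32, 32)
    K <- compute_speckle_contrast(image_stack(img))
    expect_lt(max(abs(K$K - oracle_windowed_contrast(img)), na.rm = TRUE),
              1e-10)
  }
})

test_that("K is invariant under multiplicative intensity rescaling", {
  set.seed(3)
  img <- matrix(runif(24 * 24, 5, 50), 24, 24)
  K1 <- compute_speckle_contrast(image_stack(img))
  K2 <- compute_speckle_contrast(image_stack(img * 37.5))
  expect_equal(K1$K, K2$K, tolerance = 1e-12)
})

test_that("per-frame mode averages per-frame contrast images", {
  set.seed(4)
  fr <- array(runif(3 * 16 * 16, 10, 200), c(3, 16, 16))
  st <- image_stack(fr)
  Kpf <- compute_speckle_contrast(st, mode = "per_frame")
  manual <- (oracle_windowed_contrast(fr[1, , ]) +
               oracle_windowed_contrast(fr[2, , ]) +
               oracle_windowed_contrast(fr[3, , ])) / 3
  expect_equal(Kpf$K, manual, tolerance = 1e-10)
  # literal mode instead averages frames first
  Klit <- compute_speckle_contrast(st, mode = "literal")
  avg <- apply(fr, c(2, 3), mean)
  expect_equal(Klit$K, oracle_windowed_contrast(avg), tolerance = 1e-10)
})

test_that("flow index is 1/K^2 with K = 0 flagged invalid", {
  K <- compute_speckle_contrast(image_stack(matrix(100, 9, 9), bit_depth = 8))
  ict <- contrast_to_ict(K)
  expect_false(any(ict$valid_mask))          # K = 0 everywhere valid
  Km <- K
  Km$K[5, 5] <- 0.5
  Km$K[5, 6] <- 1
  ict2 <- contrast_to_ict(Km)
  expect_equal(ict2$ict[5, 5], 4)
  expect_equal(ict2$ict[5, 6], 1)
})

test_that("stack averaging is the pixelwise mean, permutation invariant", {
  mk <- function(v) {
    m <- matrix(v, 8, 8)
    structure(list(ict = m, valid_mask = matrix(TRUE, 8, 8)),
              class = "ict_image")
  }
  icts <- lapply(1:9, mk)
  avg <- average_ict_stack(icts)
  expect_true(all(avg$ict == 5))
  perm <- average_ict_stack(icts[c(9, 3, 1, 5, 4, 2, 8, 7, 6)])
  expect_identical(avg$ict, perm$ict)
  same <- average_ict_stack(lapply(rep(4, 9), mk))
  expect_true(all(same$ict == 4))
  expect_error(average_ict_stack(icts[1:5]), class = "mesowin_param_error")
  # validity propagates: a pixel invalid in one input is invalid out
  icts[[3]]$valid_mask[2, 2] <- FALSE
  expect_false(average_ict_stack(icts)$valid_mask[2, 2])
})

test_that("rBF traces are baseline-normalized and scale invariant", {
  # length-5 value vector recycles along the frame (first) dimension
  st <- image_stack(array(c(100, 100, 180, 60, 100), c(5, 8, 8)))
  roi <- matrix(TRUE, 8, 8)
  tr <- relative_flow_trace(st, roi, baseline = 1:2)
  expect_equal(tr$rbf, c(1, 1, 1.8, 0.6, 1))
  st2 <- st
  st2$frames <- st$frames * 3.7
  expect_equal(relative_flow_trace(st2, roi, 1:2)$rbf, tr$rbf)
  expect_error(relative_flow_trace(st, roi & FALSE, 1:2),
               class = "mesowin_param_error")
})

test_that("occlusion: polygons and uniform images behave exactly", {
  img <- matrix(100, 40, 40)
  win <- matrix(TRUE, 40, 40)
  expect_equal(quantify_occlusion(img, win)$occluded_pct, 0)
  full <- list(rbind(c(0.5, 0.5), c(0.5, 40.5), c(40.5, 40.5), c(40.5, 0.5)))
  expect_equal(
    quantify_occlusion(img, win, method = "polygons", polygons = full)$occluded_pct,
    100)
  half <- list(rbind(c(0.5, 0.5), c(0.5, 20.5), c(40.5, 20.5), c(40.5, 0.5)))
  expect_equal(
    quantify_occlusion(img, win, method = "polygons", polygons = half)$occluded_pct,
    50)
  expect_error(
    quantify_occlusion(img, win, method = "polygons",
                       polygons = list(rbind(c(-5, 1), c(1, 50), c(30, 30)))),
    class = "mesowin_geometry_error")
})

test_that("auto occlusion recovers the generator's blob fraction", {
  base <- matrix(120, 256, 256)
  g <- gen_occluded_window(base, q = 0.15, n_blobs = 6, seed = 3)
  res <- quantify_occlusion(g$image)
  expect_lt(abs(res$occluded_pct - 15), 2)
  expect_true(all(res$occlusion_mask | TRUE))
  expect_gte(min(res$occluded_pct, 100), 0)
  # occlusion mask stays inside the window
  win <- matrix(FALSE, 256, 256)
  win[20:230, 20:230] <- TRUE
  g2 <- gen_occluded_window(base, q = 0.1, window_mask = win, seed = 5)
  expect_true(all(!g2$truth$blob_mask[!win]))
  res2 <- quantify_occlusion(g2$image, win)
  expect_true(all(!res2$occlusion_mask[!win]))
  expect_lt(abs(res2$occluded_pct - 10), 2)
})
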