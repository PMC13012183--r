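# Microglia preprocessing chain, Sholl ring counting against the
# brute-force ring oracle, cell counting, field-of-view arithmetic.

test_that("field of view scales inversely with zoom", {
  expect_equal(fov_from_zoom(1), 443)
  expect_equal(fov_from_zoom(2.5), 177.2)
  expect_equal(fov_from_zoom(2), 221.5)
  expect_error(fov_from_zoom(0), class = "mesowin_param_error")
})

test_that("blank images preprocess to blank binaries", {
  out <- preprocess_microglia(matrix(10, 128, 128), pixel_size_um = 0.5)
  expect_false(any(out$binary))
  expect_equal(vapply(out$provenance, `[[`, "", "step"),
               c("gaussian_blur", "rolling_ball_subtract", "otsu_binarize",
                 "remove_outliers", "min_particle", "median_filter"))
})

test_that("rolling-ball subtraction makes the result gradient invariant", {
  p <- morphology_sim_params(n_cells = 3, pixel_size_um = 0.6,
                             branch_width_um = 3.5, soma_radius_um = 5,
                             branch_length_um = 18, shape = c(360, 360),
                             noise_level = 0, seed = 51)
  g <- gen_microglia_image(p)
  flat <- g$image
  flat[!g$truth$cell_mask] <- 20                 # remove the gradient
  b_grad <- preprocess_microglia(g$image, pixel_size_um = 0.6)$binary
  b_flat <- preprocess_microglia(flat, pixel_size_um = 0.6)$binary
  iou <- sum(b_grad & b_flat) / sum(b_grad | b_flat)
  expect_gte(iou, 0.95)
})

test_that("particles below 10 px are removed, larger ones retained", {
  img <- matrix(0, 200, 200)
  img[100:102, 100:104] <- 255                   # 15 px block
  img[50, 50:54] <- 255                          # 5 px line
  img[150:159, 20:29] <- 255                     # 100 px block
  out <- preprocess_microglia(img, pixel_size_um = 1,
                              median_radius_px = 1)   # keep small shapes visible
  expect_false(any(out$binary[45:55, 45:60]))
  expect_true(any(out$binary[150:159, 20:29]))
})

test_that("k-armed stars intersect every intermediate ring exactly k times", {
  for (k in c(3, 6, 9)) {
    st <- make_star(k, L_px = 60, soma_px = 5, width_px = 2)
    pr <- sholl_profile(st$mask, st$center, step_um = 5, max_radius_um = 70,
                        pixel_size_um = 1)
    mid <- pr$radius_um > 5 & pr$radius_um < 60
    expect_true(all(pr$intersections[mid] == k))
    expect_true(all(pr$intersections[pr$radius_um > 65] == 0))
  }
})

test_that("a filled disk crosses rings once inside and never outside", {
  pts <- expand.grid(r = 1:81, c = 1:81)
  disk <- matrix((pts$r - 41)^2 + (pts$c - 41)^2 <= 27^2, 81, 81)
  pr <- sholl_profile(disk, c(41, 41), step_um = 5, max_radius_um = 40,
                      pixel_size_um = 1)
  expect_equal(pr$intersections, c(1, 1, 1, 1, 1, 0, 0, 0))
})

test_that("circle counting matches the ring-band oracle on random arbors", {
  set.seed(52)
  for (i in 1:15) {
    st <- random_star_image()
    pr <- sholl_profile(st$mask, st$center, step_um = 10, max_radius_um = 25,
                        pixel_size_um = 1)
    for (k in seq_len(nrow(pr))) {
      expect_equal(pr$intersections[k],
                   oracle_sholl_count(st$mask, st$center, pr$radius_um[k]),
                   info = sprintf("seed-case %d radius %g", i, pr$radius_um[k]))
    }
    # and both agree with the known arm count at interior radii
    expect_equal(pr$intersections, rep(st$k, nrow(pr)))
  }
})

test_that("profiles are invariant under 90-degree rotations", {
  st <- make_star(5, L_px = 40, soma_px = 4, width_px = 2, rot = 0.7)
  pr0 <- sholl_profile(st$mask, st$center, step_um = 5, max_radius_um = 45,
                       pixel_size_um = 1)
  for (rot in 1:3) {
    m <- st$mask
    for (j in seq_len(rot)) m <- t(m[nrow(m):1, ])
    prr <- sholl_profile(m, st$center, step_um = 5, max_radius_um = 45,
                         pixel_size_um = 1)
    expect_equal(prr$intersections, pr0$intersections)
  }
})

test_that("bifurcating cells double their distal intersection count", {
  p <- morphology_sim_params(n_cells = 1, n_branches = 4,
                             branch_length_um = 24, bifurcate_at_um = 12,
                             soma_radius_um = 3, branch_width_um = 1,
                             pixel_size_um = 0.0865, noise_level = 2,
                             shape = c(640, 640), seed = 53)
  g <- gen_microglia_image(p)
  bw <- preprocess_microglia(g$image, pixel_size_um = p$pixel_size_um)
  pr <- sholl_profile(bw, g$truth$centers[1, ], step_um = 4,
                      max_radius_um = 26)
  prox <- pr$radius_um > 4 & pr$radius_um < 12
  dist <- pr$radius_um > 13 & pr$radius_um < g$truth$arbor_radius_um - 1
  expect_true(all(pr$intersections[prox] == 4))
  expect_true(all(pr$intersections[dist] == 8))
})

test_that("cell counts are recovered and averaged across fields", {
  imgs <- lapply(54:56, function(s) {
    gen_microglia_image(morphology_sim_params(n_cells = 6, seed = s,
                                              noise_level = 2))$image
  })
  res <- count_cells(imgs, pixel_size_um = 0.865)
  expect_equal(res$counts, rep(6, 3))
  expect_equal(res$mean_count, 6)
  blank <- replicate(3, matrix(12, 128, 128), simplify = FALSE)
  expect_equal(count_cells(blank, pixel_size_um = 0.865)$mean_count, 0)
  expect_error(count_cells(imgs[1:2], pixel_size_um = 0.865),
               class = "mesowin_param_error")
  expect_error(count_cells(list(), pixel_size_um = 0.865),
               class = "mesowin_param_error")
})

test_that("raising the particle-size gate never raises intersection counts", {
  p <- morphology_sim_params(n_cells = 1, n_branches = 6,
                             branch_length_um = 20, soma_radius_um = 3,
                             branch_width_um = 1, pixel_size_um = 0.0865,
                             noise_level = 4, shape = c(560, 560), seed = 57)
  g <- gen_microglia_image(p)
  prev <- NULL
  for (gate in c(10, 200, 2000)) {
    bw <- preprocess_microglia(g$image, pixel_size_um = p$pixel_size_um,
                               min_particle_px = gate)
    pr <- sholl_profile(bw, g$truth$centers[1, ], step_um = 5,
                        max_radius_um = 20)
    if (!is.null(prev)) expect_true(all(pr$intersections <= prev))
    prev <- pr$intersections
  }
})

test_that("sholl guards bad centers and sub-pixel steps", {
  img <- matrix(TRUE, 20, 20)
  expect_error(sholl_profile(img, c(0, 5), pixel_size_um = 1),
               class = "mesowin_geometry_error")
  expect_error(sholl_profile(img, c(10, 10), step_um = 0.5, pixel_size_um = 1),
               class = "mesowin_param_error")
})
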