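# Interhemispheric homotopic connectivity: preprocessing chain
# (downsample -> detrend -> bandpass -> global signal regression),
# mirrored-pixel correlation about the bregma-lambda midline, Fisher z,
# and the block analysis used around cortical spreading depolarization.

midline_dir <- function(midline) {
  d <- midline$lambda_pt - midline$bregma
  d / sqrt(sum(d^2))
}

# Reflect continuous (row, col) points across the bregma-lambda line.
reflect_points <- function(pts, midline) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  d <- midline_dir(midline)
  v <- sweep(pts, 2, midline$bregma)
  proj <- drop(v %*% d)
  refl <- cbind(2 * proj * d[1], 2 * proj * d[2]) - v
  sweep(refl, 2, midline$bregma, "+")
}

# Signed side of the midline; 0 means on the line.
midline_side <- function(pts, midline) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  d <- midline_dir(midline)
  s <- d[1] * (pts[, 2] - midline$bregma[2]) -
    d[2] * (pts[, 1] - midline$bregma[1])
  s[abs(s) < 1e-9] <- 0
  sign(s)
}

#' Mirror a pixel across the anatomical midline
#'
#' Reflects a pixel across the infinite line through bregma and lambda and
#' rounds to the nearest pixel. Homotopic (left-right) pairing mirrors
#' medio-laterally across the midline itself.
#'
#' @param p `(row, col)` pixel coordinate (1-based).
#' @param midline a [midline_axis].
#' @param dm optional image dimension `(rows, cols)`; if given and the
#'   mirror falls outside, `c(NA, NA)` is returned.
#' @return integer `(row, col)` of the mirror pixel.
#' @examples
#' ml <- midline_axis(c(1, 64), c(100, 64))
#' mirror_pixel(c(10, 60), ml)  # (10, 68)
#' @export
mirror_pixel <- function(p, midline, dm = NULL) {
  q <- round(reflect_points(matrix(p, ncol = 2), midline)[1, ])
  if (!is.null(dm) && (q[1] < 1 || q[1] > dm[1] || q[2] < 1 || q[2] > dm[2])) {
    return(c(NA_real_, NA_real_))
  }
  q
}

# Homotopic pair table for an image of dimension dm: linear pixel indices
# (i on the positive side, j its mirror on the negative side). Midline
# pixels (side 0) are excluded; pairs whose mirror is unmasked or outside
# the image are dropped.
homotopic_pairs <- function(dm, midline, mask = NULL) {
  if (any(midline$bregma < 0.5) || any(midline$lambda_pt < 0.5) ||
      midline$bregma[1] > dm[1] + 0.5 || midline$bregma[2] > dm[2] + 0.5 ||
      midline$lambda_pt[1] > dm[1] + 0.5 || midline$lambda_pt[2] > dm[2] + 0.5) {
    stop_geometry("midline landmarks outside image bounds")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  pts <- cbind(rep(seq_len(dm[1]), dm[2]), rep(seq_len(dm[2]), each = dm[1]))
  side <- midline_side(pts, midline)
  cand <- which(mask & side > 0)
  if (length(cand) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  q <- round(reflect_points(pts[cand, , drop = FALSE], midline))
  inb <- q[, 1] >= 1 & q[, 1] <= dm[1] & q[, 2] >= 1 & q[, 2] <= dm[2]
  cand <- cand[inb]
  q <- q[inb, , drop = FALSE]
  jj <- q[, 1] + (q[, 2] - 1L) * dm[1]
  ok <- mask[jj] & side[jj] < 0
  data.frame(i = cand[ok], j = as.integer(jj[ok]))
}

#' Downsample a movie by block averaging
#'
#' Non-overlapping block means (e.g. 4x4 blocks for 512 -> 128); the frame
#' count is unchanged and the per-frame spatial mean is preserved exactly.
#'
#' @param movie an [image_stack].
#' @param out_size target `(rows, cols)`; input dimensions must be integer
#'   multiples.
#' @return an [image_stack].
#' @export
downsample_movie <- function(movie, out_size = c(128, 128)) {
  d <- dim(movie$frames)
  if (d[2] %% out_size[1] != 0 || d[3] %% out_size[2] != 0) {
    stop_param("input dimensions must be integer multiples of out_size")
  }
  fr <- d[2] / out_size[1]
  fc <- d[3] / out_size[2]
  if (fr == 1 && fc == 1) return(movie)
  out <- array(0, c(d[1], out_size[1], out_size[2]))
  for (f in seq_len(d[1])) {
    a <- array(movie$frames[f, , ], c(fr, out_size[1], fc, out_size[2]))
    a <- colMeans(a, dims = 1)                      # (R, fc, C)
    out[f, , ] <- colMeans(aperm(a, c(2, 1, 3)), dims = 1)
  }
  st <- movie
  st$frames <- out
  st$bit_depth <- "float"
  if (!is.null(st$pixel_size_um)) st$pixel_size_um <- st$pixel_size_um * fr
  st
}

#' Remove a per-pixel linear trend
#'
#' Subtracts the least-squares line (intercept + slope * t) from every
#' pixel's time series; residuals have zero temporal mean.
#'
#' @param movie an [image_stack] with >= 3 frames.
#' @return an [image_stack] of residuals.
#' @export
detrend_movie <- function(movie) {
  n <- n_frames(movie)
  if (n < 3) stop_param("detrending needs >= 3 frames")
  X <- cbind(1, seq_len(n))
  Y <- as_pixel_matrix(movie)
  res <- stats::lm.fit(X, Y)$residuals
  from_pixel_matrix(movie, res)
}

#' Zero-phase Butterworth bandpass per pixel
#'
#' Fourth-order Butterworth design applied forward-backward
#' ([signal::filtfilt()]), so band-interior components are not phase
#' shifted.
#'
#' @param movie an [image_stack] with `frame_rate_hz` set.
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth design order.
#' @return an [image_stack].
#' @export
bandpass_movie <- function(movie, low = 0.035, high = 0.08, order = 4) {
  fs <- movie$frame_rate_hz
  if (is.null(fs)) stop_param("movie has no frame_rate_hz")
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_param("band must satisfy 0 < low < high < frame_rate/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  Y <- as_pixel_matrix(movie)
  # remove the (out-of-band) temporal mean first: it belongs to the stop
  # band anyway and would otherwise leak edge transients into the output
  Y <- sweep(Y, 2, colMeans(Y))
  out <- matrix(0, nrow(Y), ncol(Y))
  for (j in seq_len(ncol(Y))) out[, j] <- signal::filtfilt(bf, Y[, j])
  from_pixel_matrix(movie, out)
}

#' Global signal regression
#'
#' Regresses every pixel's time series on an intercept and the global mean
#' time course over `mask`, returning the residuals.
#'
#' @param movie an [image_stack].
#' @param mask logical matrix of pixels defining the global signal
#'   (default: all pixels).
#' @return an [image_stack] of residuals.
#' @export
global_signal_regression <- function(movie, mask = NULL) {
  d <- dim(movie$frames)
  Y <- as_pixel_matrix(movie)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!any(mask)) stop_param("mask is empty")
  g <- rowMeans(Y[, as.vector(mask), drop = FALSE])
  if (stats::sd(g) < 1e-12) stop_degenerate("global signal is constant")
  res <- stats::lm.fit(cbind(1, g), Y)$residuals
  from_pixel_matrix(movie, res)
}

#' Run the connectivity preprocessing chain
#'
#' Applies, in fixed order: block-mean downsampling (identity when
#' `out_size` is `NULL`), linear detrending, zero-phase Butterworth
#' bandpass, and (optionally) global signal regression. The order is fixed
#' by design and not configurable.
#'
#' @param movie an [image_stack] with `frame_rate_hz` set.
#' @param out_size downsampling target or `NULL` to skip.
#' @param band bandpass edges in Hz.
#' @param gsr logical; apply global signal regression.
#' @param mask logical matrix (at output resolution) for the global signal.
#' @return preprocessed [image_stack].
#' @export
connectivity_preprocess <- function(movie, out_size = NULL,
                                    band = c(0.035, 0.08), gsr = TRUE,
                                    mask = NULL) {
  if (!is.null(out_size)) movie <- downsample_movie(movie, out_size)
  movie <- detrend_movie(movie)
  movie <- bandpass_movie(movie, band[1], band[2])
  if (gsr) movie <- global_signal_regression(movie, mask)
  movie
}

#' Homotopic correlation map
#'
#' For every masked pixel with a masked mirror partner in the opposite
#' hemisphere, computes the Pearson correlation of the two time series and
#' its Fisher z transform (`atanh`, with `|r|` clipped to `1 - 1e-7`).
#' Zero-variance pixels are dropped from the paired mask.
#'
#' @param movie a preprocessed [image_stack].
#' @param midline a [midline_axis] (at the movie's resolution).
#' @param mask logical brain mask (default: all pixels).
#' @return a list of class `connectivity_map` with `r_map`, `z_map`
#'   (matrices, `NA` outside pairs), `paired_mask`, and the pair table.
#' @export
homotopic_map <- function(movie, midline, mask = NULL) {
  d <- dim(movie$frames)
  pairs <- homotopic_pairs(d[2:3], midline, mask)
  Y <- as_pixel_matrix(movie)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss <- colSums(Yc^2)
  ok <- ss[pairs$i] > 1e-24 & ss[pairs$j] > 1e-24
  pairs <- pairs[ok, , drop = FALSE]
  r <- colSums(Yc[, pairs$i, drop = FALSE] * Yc[, pairs$j, drop = FALSE]) /
    sqrt(ss[pairs$i] * ss[pairs$j])
  r <- pmin(pmax(r, -1), 1)
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  r_map <- matrix(NA_real_, d[2], d[3])
  z_map <- matrix(NA_real_, d[2], d[3])
  paired <- matrix(FALSE, d[2], d[3])
  r_map[pairs$i] <- r; r_map[pairs$j] <- r
  z_map[pairs$i] <- z; z_map[pairs$j] <- z
  paired[pairs$i] <- TRUE; paired[pairs$j] <- TRUE
  structure(list(r_map = r_map, z_map = z_map, paired_mask = paired,
                 pairs = cbind(pairs, r = r, z = z)),
            class = "connectivity_map")
}

#' Interhemispheric homotopic connectivity index
#'
#' The mean Fisher z over all paired pixels of a [homotopic_map()].
#'
#' @param map a `connectivity_map`.
#' @param block_label label recorded with the result.
#' @return one-row data.frame `(block_label, value, n_pixels)`.
#' @export
connectivity_index <- function(map, block_label = NA_character_) {
  if (!any(map$paired_mask)) stop_degenerate("no paired pixels")
  data.frame(block_label = block_label,
             value = mean(map$z_map[map$paired_mask]),
             n_pixels = sum(map$paired_mask))
}

#' Connectivity block analysis around a CSD recording
#'
#' Discards the initial wave-propagation frames of the post-induction
#' movie, splits the remainder into fixed-length blocks, and runs the full
#' chain (downsample, detrend, bandpass, global signal regression,
#' homotopic map, index) on the baseline recording and on each block. When
#' the recording does not cover the final block completely, the block uses
#' the remaining frames and is flagged `short` rather than erroring.
#'
#' @param movie post-induction [image_stack] (`frame_rate_hz` set).
#' @param baseline_movie baseline [image_stack].
#' @param midline a [midline_axis] at the analysis resolution.
#' @param mask logical brain mask at the analysis resolution.
#' @param out_size downsampling target or `NULL`.
#' @param band bandpass edges (Hz).
#' @param gsr apply global signal regression.
#' @param discard_frames frames discarded at the start of `movie`.
#' @param block_minutes block length in minutes.
#' @param n_blocks number of analysis blocks.
#' @return data.frame with one row per block plus the baseline:
#'   `block_label, value, n_pixels, n_frames, short`.
#' @export
csd_block_analysis <- function(movie, baseline_movie, midline, mask = NULL,
                               out_size = NULL, band = c(0.035, 0.08),
                               gsr = TRUE, discard_frames = 500,
                               block_minutes = 10, n_blocks = 3) {
  fps <- movie$frame_rate_hz
  if (is.null(fps)) stop_param("movie has no frame_rate_hz")
  block_frames <- round(block_minutes * 60 * fps)
  total <- n_frames(movie)
  need_min <- discard_frames + (n_blocks - 1) * block_frames + 30
  if (total < need_min) {
    stop_param(sprintf(
      "insufficient frames: %d available, >= %d required (%d discard + %d blocks of %d)",
      total, need_min, discard_frames, n_blocks, block_frames))
  }
  run <- function(stk, label) {
    pre <- connectivity_preprocess(stk, out_size = out_size, band = band,
                                   gsr = gsr, mask = mask)
    idx <- connectivity_index(homotopic_map(pre, midline, mask), label)
    idx$n_frames <- n_frames(stk)
    idx
  }
  rows <- run(baseline_movie, "baseline")
  rows$short <- FALSE
  for (b in seq_len(n_blocks)) {
    a <- discard_frames + (b - 1) * block_frames + 1
    z <- min(discard_frames + b * block_frames, total)
    stk <- movie
    stk$frames <- movie$frames[a:z, , , drop = FALSE]
    row <- run(stk, paste0("block", b))
    row$short <- (z - a + 1) < block_frames
    rows <- rbind(rows, row)
  }
  rownames(rows) <- NULL
  rows
}

#' Frame bookkeeping for a block design
#'
#' Converts the discard count and recording length into minutes and block
#' coverage: how many full blocks fit after the discard and how many
#' frames remain for the last (possibly short) block.
#'
#' @param total_minutes recording length in minutes.
#' @param fps frame rate (frames/s).
#' @param discard_frames initial frames discarded.
#' @param block_minutes block length (minutes).
#' @param n_blocks number of blocks.
#' @return list with `total_frames`, `discard_minutes`, `analyzed_minutes`,
#'   `block_frames`, `frames_available`, `last_block_frames`,
#'   `last_block_short`.
#' @export
block_bookkeeping <- function(total_minutes, fps = 3, discard_frames = 500,
                              block_minutes = 10, n_blocks = 3) {
  total_frames <- round(total_minutes * 60 * fps)
  block_frames <- round(block_minutes * 60 * fps)
  avail <- total_frames - discard_frames
  last <- avail - (n_blocks - 1) * block_frames
  list(total_frames = total_frames,
       discard_minutes = discard_frames / (fps * 60),
       analyzed_minutes = avail / (fps * 60),
       block_frames = block_frames,
       frames_available = avail,
       last_block_frames = min(last, block_frames),
       last_block_short = last < block_frames)
}
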