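#' Generate a synthetic vessel field with known area fraction
#'
#' Dark curvilinear structures (smoothed random walks dilated to a random
#' width) on a bright background, emulating surface vasculature in 530-nm
#' reflectance images. Curves are added, and the last one trimmed, until
#' the foreground fraction is within 0.01 of `fraction`; the exact vessel
#' mask is returned as ground truth.
#'
#' @param fraction target vessel area fraction in `[0, 0.6]`.
#' @param shape image dimension `(rows, cols)`.
#' @param contrast relative darkening of vessels (vessel intensity is
#'   `background * (1 - contrast)`).
#' @param noise_sd white noise sd (counts).
#' @param width_px range of vessel widths (pixels).
#' @param seed RNG seed.
#' @return list with `image` (8-bit matrix) and `truth`
#'   (`fraction`, `vessel_mask`, `fraction_actual`).
#' @export
gen_vessel_image <- function(fraction, shape = c(256, 256), contrast = 0.6,
                             noise_sd = 2, width_px = c(3, 7), seed = 1) {
  if (!(fraction >= 0 && fraction <= 0.6)) {
    stop_param("fraction must be in [0, 0.6]")
  }
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  target <- fraction
  max_curves <- 2000
  curves <- 0
  while (mean(mask) < target - 0.005 && curves < max_curves) {
    curves <- curves + 1
    w <- stats::runif(1, width_px[1], width_px[2])
    pos <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
    ang <- stats::runif(1, 0, 2 * pi)
    steps <- round(0.8 * max(nr, nc))
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.15)
      pos <- pos + c(sin(ang), cos(ang))
      if (pos[1] < 1 || pos[1] > nr || pos[2] < 1 || pos[2] > nc) break
      mask <- paint_discs(mask, matrix(round(pos), 1), w / 2)
      if (s %% 20 == 0 && mean(mask) >= target - 0.005) break
    }
  }
  if (mean(mask) < target - 0.01) {
    stop_param("target vessel fraction unreachable with given widths")
  }
  bg <- 200
  img <- matrix(bg, nr, nc)
  img[mask] <- bg * (1 - contrast)
  if (noise_sd > 0) img <- img + stats::rnorm(nr * nc, 0, noise_sd)
  img <- pmin(pmax(round(img), 0), 255)
  list(image = img,
       truth = list(fraction = fraction, vessel_mask = mask,
                    fraction_actual = mean(mask)))
}

#' Superimpose near-black occlusion blobs on a window image
#'
#' Emulates drying artifacts/bubbles on an averaged LSCI image: roughly
#' circular near-black blobs whose total area inside the window mask is
#' `q` of the window, placed entirely within the window. The exact blob
#' mask is returned as ground truth.
#'
#' @param base 2-D numeric image (e.g. an averaged flow-index map scaled
#'   to 8-bit) the blobs are painted on.
#' @param q target occluded fraction in `[0, 1)`.
#' @param n_blobs number of blobs.
#' @param window_mask logical window mask (default: whole image).
#' @param seed RNG seed.
#' @return list with `image` and `truth` (`q`, `blob_mask`, `q_actual`).
#' @export
gen_occluded_window <- function(base, q, n_blobs = 5, window_mask = NULL,
                                seed = 1) {
  if (!(q >= 0 && q < 1)) stop_param("q must be in [0, 1)")
  base <- as.matrix(base)
  nr <- nrow(base); nc <- ncol(base)
  if (is.null(window_mask)) window_mask <- matrix(TRUE, nr, nc)
  win_px <- sum(window_mask)
  blob <- matrix(FALSE, nr, nc)
  if (q > 0) {
    set.seed(seed)
    target_px <- q * win_px
    r0 <- sqrt(target_px / (pi * n_blobs))
    centers_pool <- which(window_mask)
    centers <- centers_pool[sample.int(length(centers_pool), n_blobs)]
    centers <- cbind((centers - 1) %% nr + 1, (centers - 1) %/% nr + 1)
    for (b in seq_len(n_blobs - 1)) {
      blob <- paint_discs(blob, centers[b, , drop = FALSE],
                          r0 * stats::runif(1, 0.8, 1.2))
      blob <- blob & window_mask
    }
    # last blob: binary-search the radius onto the target area
    lo <- 0; hi <- 2.5 * r0 + 2
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      cand <- paint_discs(blob, centers[n_blobs, , drop = FALSE], mid) &
        window_mask
      if (sum(cand) < target_px) lo <- mid else hi <- mid
    }
    blob <- paint_discs(blob, centers[n_blobs, , drop = FALSE], hi) &
      window_mask
  }
  img <- base
  img[blob] <- round(0.02 * stats::median(base[window_mask]))
  list(image = img,
       truth = list(q = q, blob_mask = blob, q_actual = sum(blob) / win_px))
}
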