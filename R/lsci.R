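# Laser speckle contrast imaging: windowed contrast K, the 1/K^2 flow
# index, stack averaging, relative-blood-flow traces and occluded-area
# quantification.

contrast_image <- function(K, valid_mask, window_px, mode) {
  structure(list(K = K, valid_mask = valid_mask, window_px = window_px,
                 mode = mode),
            class = "contrast_image")
}

ict_image <- function(ict, valid_mask) {
  structure(list(ict = ict, valid_mask = valid_mask), class = "ict_image")
}

#' @export
print.contrast_image <- function(x, ...) {
  cat(sprintf("<contrast_image> %d x %d, window %d, mode '%s', mean K %.4f\n",
              nrow(x$K), ncol(x$K), x$window_px, x$mode,
              mean(x$K[x$valid_mask])))
  invisible(x)
}

#' @export
print.ict_image <- function(x, ...) {
  cat(sprintf("<ict_image> %d x %d, mean flow index %.4f\n",
              nrow(x$ict), ncol(x$ict), mean(x$ict[x$valid_mask])))
  invisible(x)
}

#' Spatial speckle contrast
#'
#' Computes the speckle contrast image K = sd/mean over a sliding
#' `window_px` x `window_px` window. In `"literal"` mode the raw frames of
#' the set are first averaged temporally and K is computed on the averaged
#' image; in `"per_frame"` mode K is computed on each raw frame and the K
#' images are averaged. The border of half-window width is flagged invalid
#' (no padding); pixels whose window mean is zero are flagged invalid, not
#' errors. The sample standard deviation uses the n - 1 denominator.
#'
#' @param stack an [image_stack] of raw speckle frames (or a matrix for a
#'   single frame).
#' @param window_px odd window width (default 7).
#' @param mode `"literal"` (average frames, then K) or `"per_frame"`
#'   (K per frame, then average). `"literal"` follows the stated processing
#'   order; averaging K images is the more common field practice and is
#'   offered explicitly.
#' @return a `contrast_image` with fields `K` (NA where invalid) and
#'   `valid_mask`.
#' @export
compute_speckle_contrast <- function(stack, window_px = 7,
                                     mode = c("literal", "per_frame")) {
  mode <- match.arg(mode)
  if (is.matrix(stack)) stack <- image_stack(stack)
  if (window_px %% 2 != 1) stop_param("window_px must be odd")
  d <- dim(stack$frames)
  if (window_px > min(d[2], d[3])) stop_param("window larger than image")
  one_K <- function(img) {
    n <- window_px^2
    mu0 <- mean(img)                       # global centering for stability
    xc <- img - mu0
    S1 <- box_sum(xc, window_px)
    S2 <- box_sum(xc^2, window_px)
    muc <- S1 / n
    v <- pmax(S2 - n * muc^2, 0) / (n - 1)
    mu <- muc + mu0
    K <- sqrt(v) / mu
    K[!is.na(mu) & abs(mu) < 1e-12] <- NA
    K
  }
  if (mode == "literal") {
    avg <- apply(stack$frames, c(2, 3), mean)
    K <- one_K(avg)
  } else {
    Ks <- lapply(seq_len(d[1]), function(i) one_K(stack$frames[i, , ]))
    K <- Reduce(`+`, Ks) / d[1]
  }
  contrast_image(K, valid_mask = !is.na(K), window_px = window_px, mode = mode)
}

#' Convert speckle contrast to the 1/K^2 flow index
#'
#' @param K a `contrast_image`.
#' @return an `ict_image`; pixels with K = 0 (or invalid K) are flagged
#'   invalid rather than producing infinities.
#' @export
contrast_to_ict <- function(K) {
  stopifnot(inherits(K, "contrast_image"))
  valid <- K$valid_mask & !is.na(K$K) & K$K > 0
  ict <- matrix(NA_real_, nrow(K$K), ncol(K$K))
  ict[valid] <- 1 / K$K[valid]^2
  ict_image(ict, valid)
}

#' Average a stack of flow-index images
#'
#' Averages consecutive non-overlapping groups of `stack_size` images
#' pixelwise; an output pixel is valid only where all contributing inputs
#' are valid.
#'
#' @param icts list of `ict_image` objects with identical dimensions.
#' @param stack_size images averaged per output (default 9).
#' @return a single `ict_image` when one group fits, otherwise a list of
#'   them.
#' @export
average_ict_stack <- function(icts, stack_size = 9) {
  if (length(icts) < stack_size) {
    stop_param(sprintf("need >= %d images, got %d", stack_size, length(icts)))
  }
  dms <- vapply(icts, function(x) dim(x$ict), integer(2))
  if (any(dms[1, ] != dms[1, 1]) || any(dms[2, ] != dms[2, 1])) {
    stop_param("flow-index images have mismatched shapes")
  }
  n_groups <- length(icts) %/% stack_size
  out <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    grp <- icts[((g - 1) * stack_size + 1):(g * stack_size)]
    valid <- Reduce(`&`, lapply(grp, `[[`, "valid_mask"))
    acc <- matrix(0, dms[1, 1], dms[2, 1])
    for (x in grp) acc <- acc + ifelse(x$valid_mask, x$ict, 0)
    m <- matrix(NA_real_, dms[1, 1], dms[2, 1])
    m[valid] <- acc[valid] / stack_size
    out[[g]] <- ict_image(m, valid)
  }
  if (n_groups == 1) out[[1]] else out
}

#' Relative blood-flow trace over an ROI
#'
#' rBF(t) is the ROI-mean flow index at frame t divided by its mean over
#' the baseline frames, so the trace averages to 1 over the baseline and
#' is invariant to any positive rescaling of the input.
#'
#' @param ict_movie list of `ict_image` objects, or an [image_stack] whose
#'   frames are flow-index maps.
#' @param roi logical ROI mask.
#' @param baseline integer vector of baseline frame indices (must precede
#'   the event frames of interest).
#' @return data.frame `(frame, rbf)`.
#' @export
relative_flow_trace <- function(ict_movie, roi, baseline) {
  if (inherits(ict_movie, "image_stack")) {
    vals <- apply(ict_movie$frames, 1, function(fr) mean(fr[roi]))
  } else {
    vals <- vapply(ict_movie, function(x) {
      m <- roi & x$valid_mask
      if (!any(m)) NA_real_ else mean(x$ict[m])
    }, numeric(1))
  }
  if (!any(roi)) stop_param("empty ROI")
  if (length(baseline) == 0 || any(baseline < 1) ||
      any(baseline > length(vals))) {
    stop_param("baseline frame range empty or out of bounds")
  }
  b <- mean(vals[baseline])
  data.frame(frame = seq_along(vals), rbf = vals / b)
}

#' Quantify the occluded window area on an LSCI image
#'
#' Occluded regions (drying artifacts, bubbles) appear near-black on
#' averaged LSCI images. `"polygons"` reproduces manual delineation: the
#' occluded area is the union of the supplied polygons intersected with
#' the window. `"auto"` thresholds at a small fraction of the
#' within-window intensity range (`t = min + dark_frac * (max - min)`) and
#' keeps connected dark components of at least `min_area_px` pixels; a
#' contrast-free window reports nothing occluded.
#'
#' @param img an `ict_image`, `contrast_image`, or plain matrix.
#' @param window_mask logical window mask.
#' @param method `"auto"` or `"polygons"`.
#' @param polygons list of `(row, col)` vertex matrices (for
#'   `"polygons"`).
#' @param dark_frac fraction of the within-window intensity range defining
#'   "near-black" (auto method).
#' @param min_area_px minimum connected dark component size (auto method).
#' @return list with `occluded_pct` (0-100) and `occlusion_mask`
#'   (subset of the window).
#' @export
quantify_occlusion <- function(img, window_mask = NULL,
                               method = c("auto", "polygons"),
                               polygons = NULL, dark_frac = 0.02,
                               min_area_px = 50) {
  method <- match.arg(method)
  m <- if (inherits(img, "ict_image")) img$ict else
    if (inherits(img, "contrast_image")) img$K else as.matrix(img)
  if (is.null(window_mask)) window_mask <- !is.na(m)
  if (!any(window_mask)) stop_param("window mask is empty")
  if (method == "polygons") {
    occ <- matrix(FALSE, nrow(m), ncol(m))
    for (pg in polygons %||% list()) {
      occ <- occ | polygon_mask(pg, dim(m))
    }
    occ <- occ & window_mask
  } else {
    vals <- m[window_mask & !is.na(m)]
    rng <- range(vals)
    if (rng[2] <= rng[1]) {
      occ <- matrix(FALSE, nrow(m), ncol(m))   # no contrast, nothing occluded
    } else {
      thr <- rng[1] + dark_frac * (rng[2] - rng[1])
      dark <- !is.na(m) & m <= thr & window_mask
      occ <- filter_small_components(dark, min_area_px) & window_mask
    }
  }
  list(occluded_pct = 100 * sum(occ) / sum(window_mask),
       occlusion_mask = occ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
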