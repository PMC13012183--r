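# Microglia counting and Sholl analysis: the fixed preprocessing chain
# (blur -> rolling-ball background subtraction -> Otsu -> outlier removal
# -> particle filtering -> median filter) and ring-intersection counting.

#' Preprocess a microglia maximum projection to a binary cell image
#'
#' Applies, in fixed order: Gaussian blur (sigma 0.5 px), rolling-ball
#' background subtraction (implemented as grayscale opening with a disc
#' structuring element of the given radius, subtracted from the image),
#' Otsu binarization (bright cells are the foreground class), outlier
#' removal (a pixel is replaced by the median of its radius-2 disc
#' neighbourhood when it deviates from it by more than the threshold on
#' the 0-255 scale; on a binary image this despeckles isolated flipped
#' pixels), removal of connected components below the minimum particle
#' size (8-connectivity), and a radius-5 median filter.
#'
#' @param image grayscale matrix (8-bit scale assumed when max > 1).
#' @param pixel_size_um um per pixel, carried into the result.
#' @param blur_sigma Gaussian blur sigma (px).
#' @param rolling_ball_px rolling-ball radius (px).
#' @param outlier_radius_px outlier-removal neighbourhood radius (px).
#' @param outlier_threshold outlier deviation threshold (0-255 scale).
#' @param min_particle_px minimum connected component size (px).
#' @param median_radius_px final median filter radius (px).
#' @return a list of class `binary_cell_image` with `binary` (logical
#'   matrix), `pixel_size_um`, and `provenance` (ordered applied steps).
#' @export
preprocess_microglia <- function(image, pixel_size_um = NULL,
                                 blur_sigma = 0.5, rolling_ball_px = 50,
                                 outlier_radius_px = 2,
                                 outlier_threshold = 50,
                                 min_particle_px = 10,
                                 median_radius_px = 5) {
  image <- as.matrix(image)
  if (length(dim(image)) != 2) stop_param("input must be a 2-D grayscale image")
  img <- if (max(image) > 1) image / 255 else image
  prov <- list()

  img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
  prov <- c(prov, list(list(step = "gaussian_blur", sigma = blur_sigma)))

  brush <- EBImage::makeBrush(2 * rolling_ball_px + 1, shape = "disc")
  bg <- as.matrix(EBImage::opening(img, brush))
  img <- pmax(img - bg, 0)
  prov <- c(prov, list(list(step = "rolling_ball_subtract",
                            radius_px = rolling_ball_px)))

  if (max(img) <= min(img)) {
    bin <- matrix(FALSE, nrow(img), ncol(img))
    prov <- c(prov, list(list(step = "otsu_binarize", threshold = NA)))
  } else {
    thr <- otsu_threshold(img)
    bin <- img > thr
    prov <- c(prov, list(list(step = "otsu_binarize", threshold = thr * 255)))
  }

  b01 <- matrix(as.numeric(bin), nrow(bin), ncol(bin))
  med <- as.matrix(EBImage::medianFilter(b01, outlier_radius_px))
  dev <- abs(b01 - med) * 255
  b01[dev > outlier_threshold] <- med[dev > outlier_threshold]
  bin <- b01 > 0.5
  prov <- c(prov, list(list(step = "remove_outliers",
                            radius_px = outlier_radius_px,
                            threshold = outlier_threshold)))

  bin <- filter_small_components(bin, min_particle_px)
  prov <- c(prov, list(list(step = "min_particle",
                            min_px = min_particle_px)))

  b01 <- matrix(as.numeric(bin), nrow(bin), ncol(bin))
  bin <- as.matrix(EBImage::medianFilter(b01, median_radius_px)) > 0.5
  prov <- c(prov, list(list(step = "median_filter",
                            radius_px = median_radius_px)))

  structure(list(binary = bin, pixel_size_um = pixel_size_um,
                 provenance = prov),
            class = "binary_cell_image")
}

# Count maximal contiguous TRUE runs on a closed circle of samples,
# merging the run that wraps the 0/2pi seam.
count_circular_runs <- function(fg) {
  if (!any(fg)) return(0L)
  if (all(fg)) return(1L)
  r <- rle(fg)
  n <- sum(r$values)
  if (fg[1] && fg[length(fg)]) n <- n - 1L
  as.integer(n)
}

#' Sholl ring-intersection profile of one cell
#'
#' Draws concentric circles of `step_um` spacing around the soma center,
#' samples each circle at no more than 1-px arc spacing, and counts the
#' maximal contiguous foreground arcs (runs wrapping the angular seam are
#' merged). The maximum radius defaults to the distance from the center to
#' the nearest image border.
#'
#' @param cell a `binary_cell_image` (with `pixel_size_um` set), or a
#'   logical matrix plus `pixel_size_um`.
#' @param center `(row, col)` soma center (1-based).
#' @param step_um ring spacing in micrometers (default 5).
#' @param max_radius_um largest ring radius in micrometers.
#' @param pixel_size_um um per pixel (when `cell` is a plain matrix).
#' @return a data.frame of class `sholl_profile` with columns
#'   `radius_um, intersections`.
#' @export
sholl_profile <- function(cell, center, step_um = 5, max_radius_um = NULL,
                          pixel_size_um = NULL) {
  if (inherits(cell, "binary_cell_image")) {
    binary <- cell$binary
    pixel_size_um <- pixel_size_um %||% cell$pixel_size_um
  } else {
    binary <- as.matrix(cell) > 0.5
  }
  if (is.null(pixel_size_um)) stop_param("pixel_size_um is required")
  nr <- nrow(binary); nc <- ncol(binary)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc) {
    stop_geometry("center lies outside the image")
  }
  if (step_um / pixel_size_um < 1) {
    stop_param("ring step must be at least one pixel")
  }
  if (is.null(max_radius_um)) {
    max_radius_um <- (min(center[1] - 1, nr - center[1],
                          center[2] - 1, nc - center[2])) * pixel_size_um
  }
  radii <- seq(step_um, max_radius_um, by = step_um)
  if (length(radii) == 0) stop_param("max_radius_um smaller than one step")
  counts <- integer(length(radii))
  for (k in seq_along(radii)) {
    r_px <- radii[k] / pixel_size_um
    nsamp <- max(16L, ceiling(2 * pi * r_px))
    th <- 2 * pi * (seq_len(nsamp) - 1) / nsamp
    rr <- pmin(pmax(round(center[1] + r_px * sin(th)), 1), nr)
    cc <- pmin(pmax(round(center[2] + r_px * cos(th)), 1), nc)
    counts[k] <- count_circular_runs(binary[cbind(rr, cc)])
  }
  structure(data.frame(radius_um = radii, intersections = counts),
            class = c("sholl_profile", "data.frame"),
            center = center, step_um = step_um)
}

#' Count cells across replicate maximum-projection fields
#'
#' Each field is preprocessed with [preprocess_microglia()] and the number
#' of connected components (8-connectivity, already size-gated by the
#' minimum-particle step) is counted; the per-field counts and their mean
#' are returned.
#'
#' @param max_projections list of grayscale matrices (one per section).
#' @param pixel_size_um um per pixel.
#' @param n_projections expected number of fields (default 3 sections).
#' @param ... passed to [preprocess_microglia()].
#' @return list with `counts` (per field) and `mean_count`.
#' @export
count_cells <- function(max_projections, pixel_size_um = NULL,
                        n_projections = 3, ...) {
  if (length(max_projections) == 0) stop_param("no projection images supplied")
  if (length(max_projections) != n_projections) {
    stop_param(sprintf("expected %d projections, got %d", n_projections,
                       length(max_projections)))
  }
  counts <- vapply(max_projections, function(im) {
    bw <- preprocess_microglia(im, pixel_size_um = pixel_size_um, ...)
    max(label_components(bw$binary))
  }, numeric(1))
  list(counts = counts, mean_count = mean(counts))
}

#' Field of view under digital zoom
#'
#' @param zoom zoom factor (> 0).
#' @param base_fov_um unzoomed field of view in micrometers.
#' @return field of view in micrometers (`base_fov_um / zoom`).
#' @examples
#' fov_from_zoom(2.5)  # 177.2
#' @export
fov_from_zoom <- function(zoom, base_fov_um = 443) {
  if (!(zoom > 0)) stop_param("zoom must be > 0")
  base_fov_um / zoom
}
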