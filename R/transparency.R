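# Window-transparency statistic: Otsu auto-thresholding of brain-masked
# reflectance images and the percentage of pixels occupied by vasculature.

#' Otsu threshold of masked pixels
#'
#' Candidate thresholds are the interior edges of a 256-bin grid spanning
#' the min-max of the masked pixels (regardless of bit depth, so 8- and
#' 16-bit inputs behave identically); the between-class variance of the
#' exact masked values split at each candidate is maximized. Pixels
#' outside the mask never influence the threshold. Ties take the lowest
#' threshold.
#'
#' @param image numeric matrix.
#' @param mask logical matrix (default: all pixels).
#' @param n_bins histogram bins (default 256).
#' @return threshold intensity (scalar); the lower class is
#'   `intensity <= threshold`.
#' @export
otsu_threshold <- function(image, mask = NULL, n_bins = 256) {
  image <- as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  vals <- image[mask]
  if (length(vals) == 0) stop_param("mask is empty")
  lo <- min(vals)
  hi <- max(vals)
  if (hi <= lo) stop_degenerate("constant masked region: no threshold exists")
  edges <- seq(lo, hi, length.out = n_bins + 1)[-c(1, n_bins + 1)]
  v <- sort(vals)
  n <- length(v)
  cum <- cumsum(v)
  tot <- cum[n]
  idx <- findInterval(edges, v)           # count of values <= each edge
  valid <- idx > 0 & idx < n
  w0 <- idx / n
  mu0 <- cum[pmax(idx, 1)] / pmax(idx, 1)
  mu1 <- (tot - cum[pmax(idx, 1)]) / pmax(n - idx, 1)
  sigma_b <- rep(-Inf, length(edges))
  sigma_b[valid] <- (w0 * (1 - w0) * (mu0 - mu1)^2)[valid]
  edges[which.max(sigma_b)]
}

#' Vessel area fraction of a brain-masked reflectance image
#'
#' Binarizes the masked image at the Otsu threshold and reports the dark
#' (below-threshold) class as vasculature: at 530 nm hemoglobin absorbs,
#' so vessels appear dark on the bright parenchyma. The percentage of
#' masked pixels classified as vessel is the transparency statistic —
#' a clear window resolves more vasculature. Artifact or inflammation
#' regions can be excluded by polygons subtracted from the mask before
#' thresholding.
#'
#' @param image numeric matrix.
#' @param mask logical brain mask, or `NULL` for the whole image.
#' @param polarity only `"dark_vessels"` is defined.
#' @param exclude optional list of `(row, col)` polygon vertex matrices
#'   removed from the mask.
#' @param day_label label recorded with the record (e.g. `"Day 1"`).
#' @return one-row data.frame `(day_label, vasculature_pct,
#'   threshold_used, n_masked_px)`.
#' @export
vessel_area_fraction <- function(image, mask = NULL,
                                 polarity = "dark_vessels",
                                 exclude = NULL, day_label = NA_character_) {
  polarity <- match.arg(polarity, "dark_vessels")
  image <- as.matrix(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  for (pg in exclude %||% list()) {
    mask <- mask & !polygon_mask(pg, dim(image))
  }
  if (!any(mask)) stop_param("mask is empty after exclusions")
  thr <- otsu_threshold(image, mask)
  vessel <- mask & image <= thr
  data.frame(day_label = day_label,
             vasculature_pct = 100 * sum(vessel) / sum(mask),
             threshold_used = thr,
             n_masked_px = sum(mask))
}

#' Longitudinal change in vasculature percentage
#'
#' @param records data.frame of per-day records (rows from
#'   [vessel_area_fraction()]).
#' @param reference_day label of the reference day.
#' @return data.frame `(day_label, vasculature_pct, delta_vs_reference)`;
#'   the reference row has delta 0.
#' @export
longitudinal_change <- function(records, reference_day = "Day 1") {
  if (!reference_day %in% records$day_label) {
    stop_param(sprintf("reference day '%s' not present", reference_day))
  }
  ref <- records$vasculature_pct[match(reference_day, records$day_label)]
  data.frame(day_label = records$day_label,
             vasculature_pct = records$vasculature_pct,
             delta_vs_reference = records$vasculature_pct - ref)
}
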