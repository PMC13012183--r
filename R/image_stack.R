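#' Image stack container
#'
#' A minimal container for grayscale image stacks: a 3-D numeric array
#' indexed `(frame, row, col)` plus acquisition metadata. Single images are
#' stored as 1-frame stacks. Intensities are kept on their native integer
#' scale (0..255 for 8-bit, 0..65535 for 16-bit); derived floating-point
#' maps use `bit_depth = "float"`.
#'
#' @param frames numeric matrix (one frame) or 3-D array `(frame, row, col)`.
#' @param bit_depth 8, 16 or `"float"`.
#' @param pixel_size_um physical pixel size in micrometers (optional).
#' @param frame_rate_hz acquisition frame rate in frames/s (optional).
#' @param exposure_ms exposure time per frame in ms (optional).
#' @return an object of class `image_stack`.
#' @examples
#' s <- image_stack(array(runif(2 * 4 * 4, 0, 255), c(2, 4, 4)), bit_depth = 8)
#' n_frames(s)
#' @export
image_stack <- function(frames, bit_depth = "float", pixel_size_um = NULL,
                        frame_rate_hz = NULL, exposure_ms = NULL) {
  if (is.matrix(frames)) {
    frames <- array(frames, c(1L, nrow(frames), ncol(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop_format("frames must be a matrix or a 3-D (frame, row, col) array")
  }
  if (anyNA(frames) || any(frames < 0)) {
    stop_format("intensities must be non-negative and non-missing")
  }
  if (!identical(bit_depth, "float")) {
    if (!bit_depth %in% c(8, 16)) stop_param("bit_depth must be 8, 16 or 'float'")
    if (max(frames) > 2^bit_depth - 1) {
      stop_format(sprintf("intensities exceed %d-bit range", bit_depth))
    }
  }
  structure(
    list(frames = frames, bit_depth = bit_depth,
         pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
         exposure_ms = exposure_ms),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d, bit depth %s\n",
              d[1], d[2], d[3], as.character(x$bit_depth)))
  if (!is.null(x$frame_rate_hz)) cat("  frame rate:", x$frame_rate_hz, "Hz\n")
  if (!is.null(x$exposure_ms)) cat("  exposure:", x$exposure_ms, "ms\n")
  if (!is.null(x$pixel_size_um)) cat("  pixel size:", x$pixel_size_um, "um\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an [image_stack].
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Extract one frame as a matrix
#' @param stack an [image_stack].
#' @param i frame index.
#' @return numeric matrix `(row, col)`.
#' @export
get_frame <- function(stack, i) {
  stack$frames[i, , ]
}

# (frames, rows, cols) array <-> (n_frames x n_pixels) matrix. Because the
# frame index comes first, column-major reshaping keeps each pixel's time
# series contiguous in one column.
as_pixel_matrix <- function(stack) {
  d <- dim(stack$frames)
  matrix(stack$frames, nrow = d[1])
}

from_pixel_matrix <- function(stack, m) {
  d <- dim(stack$frames)
  out <- stack
  out$frames <- array(m, d)
  out$bit_depth <- "float"
  out
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an [image_stack].
#' Metadata (pixel size, frame rate, exposure, and the offset/scale used
#' for float maps) is restored from a JSON sidecar with the same basename
#' when present.
#'
#' @param path path to a `.tif` file.
#' @return an [image_stack].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop_format(paste("cannot read TIFF:", conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) > 2) stop_format("non-grayscale TIFF (multiple channels)")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("inconsistent page shapes in TIFF stack")
  }
  frames <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]

  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)

  bits <- attr(pages[[1]], "bits.per.sample")
  bit_depth <- if (!is.null(meta$bit_depth)) {
    meta$bit_depth
  } else if (!is.null(bits) && bits %in% c(8, 16)) {
    as.numeric(bits)
  } else {
    "float"
  }
  if (identical(bit_depth, "float")) {
    # float pages come back in [0, 1]; undo the recorded affine map
    off <- if (!is.null(meta$float_offset)) meta$float_offset else 0
    sc <- if (!is.null(meta$float_scale)) meta$float_scale else 1
    frames <- pmax(frames * sc + off, 0)
  } else {
    # integer pages come back normalized to [0, 1]; restore counts exactly
    frames <- round(frames * (2^bit_depth - 1))
  }
  image_stack(frames, bit_depth = bit_depth,
              pixel_size_um = meta$pixel_size_um,
              frame_rate_hz = meta$frame_rate_hz,
              exposure_ms = meta$exposure_ms)
}

#' Write a grayscale TIFF stack
#'
#' Integer stacks (bit depth 8/16) round-trip bit-exactly. Float stacks are
#' min-max scaled into `[0, 1]`, stored as 32-bit float pages, and the
#' offset/scale recorded in the JSON sidecar so [read_stack()] restores the
#' original values (to float32 precision).
#'
#' @param stack an [image_stack].
#' @param path output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  meta <- list(bit_depth = stack$bit_depth,
               pixel_size_um = stack$pixel_size_um,
               frame_rate_hz = stack$frame_rate_hz,
               exposure_ms = stack$exposure_ms)
  if (identical(stack$bit_depth, "float")) {
    lo <- min(stack$frames)
    hi <- max(stack$frames)
    sc <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[1]), function(i) {
      (stack$frames[i, , ] - lo) / sc
    })
    meta$float_offset <- lo
    meta$float_scale <- sc
    ok <- tryCatch(
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none"),
      error = function(e) stop_format(paste("cannot write TIFF:", conditionMessage(e)))
    )
  } else {
    den <- 2^stack$bit_depth - 1
    pages <- lapply(seq_len(d[1]), function(i) stack$frames[i, , ] / den)
    ok <- tryCatch(
      tiff::writeTIFF(pages, path,
                      bits.per.sample = as.integer(stack$bit_depth),
                      compression = "none"),
      error = function(e) stop_format(paste("cannot write TIFF:", conditionMessage(e)))
    )
  }
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary mask as an 8-bit {0, 255} TIFF
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_stack(image_stack(matrix(as.numeric(mask) * 255, nrow(mask), ncol(mask)),
                          bit_depth = 8), path)
}
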