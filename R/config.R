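#' Analysis configuration
#'
#' Bundles the processing constants used across the pipeline: the speckle
#' contrast window, the hemodynamic bandpass, the post-CSD frame discard
#' and block length, and the Sholl ring step.
#'
#' @param window_px odd sliding-window width for speckle contrast (pixels).
#' @param band_low_hz,band_high_hz hemodynamic bandpass edges in Hz.
#' @param discard_frames frames dropped at the start of a post-CSD recording
#'   (the wave-propagation period).
#' @param block_minutes length of each analysis block in minutes.
#' @param sholl_step_um Sholl ring spacing in micrometers.
#' @param set_size raw speckle frames per image set.
#' @param stack_size flow-index images averaged per output stack.
#' @param seed integer seed recorded with the run (optional).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(window_px = 7, band_low_hz = 0.035,
                            band_high_hz = 0.08, discard_frames = 500,
                            block_minutes = 10, sholl_step_um = 5,
                            set_size = 15, stack_size = 9, seed = NULL) {
  if (!is_count(window_px) || window_px %% 2 != 1 || window_px < 3) {
    stop_param("window_px must be an odd integer >= 3")
  }
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz)) {
    stop_param("need 0 < band_low_hz < band_high_hz")
  }
  for (v in list(discard_frames, block_minutes, sholl_step_um, set_size,
                 stack_size)) {
    if (!(is.numeric(v) && length(v) == 1 && v > 0)) {
      stop_param("all counts must be positive scalars")
    }
  }
  structure(
    list(window_px = as.integer(window_px), band_low_hz = band_low_hz,
         band_high_hz = band_high_hz, discard_frames = as.integer(discard_frames),
         block_minutes = block_minutes, sholl_step_um = sholl_step_um,
         set_size = as.integer(set_size), stack_size = as.integer(stack_size),
         seed = seed),
    class = "analysis_config"
  )
}

#' Read / write an analysis configuration as JSON
#' @param path JSON file path.
#' @return [read_config()] returns an `analysis_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, x[intersect(names(x), names(formals(analysis_config)))])
}

#' @param config an `analysis_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Midline axis from skull landmarks
#'
#' The anatomical midline is the line through bregma and lambda; it defines
#' the left/right hemisphere split and the mirror geometry used for
#' homotopic pixel pairing. Coordinates are 1-based `(row, col)` pixel
#' positions and may be fractional.
#'
#' @param bregma,lambda_pt numeric `(row, col)` landmark coordinates.
#' @return a list of class `midline_axis`.
#' @export
midline_axis <- function(bregma, lambda_pt) {
  bregma <- as.numeric(bregma)
  lambda_pt <- as.numeric(lambda_pt)
  if (length(bregma) != 2 || length(lambda_pt) != 2) {
    stop_geometry("landmarks must be (row, col) pairs")
  }
  if (all(abs(bregma - lambda_pt) < 1e-12)) {
    stop_geometry("bregma and lambda must differ")
  }
  structure(list(bregma = bregma, lambda_pt = lambda_pt),
            class = "midline_axis")
}

#' Read / write landmark JSON (`{"bregma": [r, c], "lambda": [r, c]}`)
#' @param path JSON file path.
#' @return [read_landmarks()] returns a [midline_axis].
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$bregma) || is.null(x$lambda)) {
    stop_format("landmark JSON needs 'bregma' and 'lambda'")
  }
  midline_axis(x$bregma, x$lambda)
}

#' @param midline a [midline_axis].
#' @rdname read_landmarks
#' @export
write_landmarks <- function(midline, path) {
  jsonlite::write_json(list(bregma = midline$bregma, lambda = midline$lambda_pt),
                       path, digits = NA)
  invisible(path)
}

#' Write records to CSV with a deterministic schema
#'
#' @param rows a data.frame (possibly 0-row); column order is preserved.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop_mesowin(paste("cannot write table:", conditionMessage(e)),
                                      "mesowin_io_error"))
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
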