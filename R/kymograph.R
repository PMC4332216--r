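#' Calibrated space-time linescan image
#'
#' A kymograph is a 2-D intensity array whose rows are successive scans of a
#' fixed line over time and whose columns are spatial positions along the
#' scan path. Moving red blood cells appear as oblique dark streaks; the
#' streak slope (pixels per line) encodes their velocity.
#'
#' @param image Numeric matrix; rows = scan lines in time order, columns =
#'   spatial pixels. At least 16 rows and 16 columns.
#' @param line_rate Line (scan) rate in Hz.
#' @param pixel_size Spatial pixel size in micrometres per pixel.
#' @param truth Optional ground-truth descriptor (see [kymograph_truth()])
#'   attached by the synthetic generator.
#'
#' @return An object of class `"kymograph"`: a list with elements `image`,
#'   `line_rate`, `pixel_size` and (optionally) `truth`.
#' @seealso [generate_kymograph()], [estimate_velocity()],
#'   [read_kymograph_tiff()]
#' @export
kymograph <- function(image, line_rate, pixel_size, truth = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    pf_stop("`image` must be a numeric matrix (rows = time, columns = space)")
  if (nrow(image) < 16L || ncol(image) < 16L)
    pf_stop("kymograph must have at least 16 rows and 16 columns", "data")
  if (!is.numeric(line_rate) || length(line_rate) != 1L || line_rate <= 0)
    pf_stop("`line_rate` must be a single positive number (Hz)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    pf_stop("`pixel_size` must be a single positive number (um/pixel)")
  structure(list(image = image, line_rate = line_rate,
                 pixel_size = pixel_size, truth = truth),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  dur <- nrow(x$image) / x$line_rate
  cat(sprintf("kymograph: %d lines x %d px (%.3f s at %g Hz, %g um/px)\n",
              nrow(x$image), ncol(x$image), dur, x$line_rate, x$pixel_size))
  if (!is.null(x$truth))
    cat(sprintf("  synthetic truth: velocity %g mm/s, seed %d\n",
                x$truth$velocity, x$truth$seed))
  invisible(x)
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("velocity estimate: %.4g mm/s (%s; %d/%d windows accepted, %.1f s accepted)\n",
              x$velocity, x$method, sum(x$per_window$accepted),
              nrow(x$per_window), x$accepted_duration))
  if (x$below_standard)
    cat("  flag: accepted duration below the 40 s quality standard\n")
  invisible(x)
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat(sprintf("FWHM diameter: %.4g um (half-max %.3g between %.4g and %.4g um)\n",
              x$diameter, x$half_max_level, x$crossings[1], x$crossings[2]))
  invisible(x)
}
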