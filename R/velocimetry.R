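# cache of precomputed projection bin tables for the default coarse grid,
# keyed by window shape; windowed estimation reuses one table thousands of
# times, skipping per-pixel trigonometry
.radon_cache <- new.env(parent = emptyenv())

coarse_scan_cached <- function(block, coarse, max_angle, coarse_step) {
  if (max_angle != 89 || coarse_step != 1)
    return(radon_angle_scan(block, coarse))
  key <- paste(nrow(block), ncol(block), sep = "x")
  tab <- .radon_cache[[key]]
  if (is.null(tab)) {
    tab <- radon_bin_table(nrow(block), ncol(block), coarse)
    .radon_cache[[key]] <- tab
  }
  radon_variance_binned(block, tab)
}

#' Projection-variance angle scan of a kymograph block
#'
#' Evaluates the Radon streak-angle objective at a vector of candidate
#' angles: each pixel of the (mean-subtracted) block is projected onto the
#' axis perpendicular to the candidate streak direction, accumulated into
#' unit-width bins, and the count-weighted variance of the bin means is
#' returned per angle. Angles are measured in degrees from the time (row)
#' axis, so `tan(angle)` is the streak slope in pixels per line. The
#' objective peaks when the projection runs along the streaks.
#'
#' @param block Numeric matrix (rows = scan lines, columns = spatial
#'   pixels), already mean-subtracted.
#' @param angles_deg Numeric vector of candidate angles in degrees, inside
#'   (-90, 90).
#' @return Numeric vector of projection variances, one per angle.
#' @seealso [radon_window_velocity()]
#' @export
radon_angle_scan <- function(block, angles_deg) {
  if (!is.matrix(block) || !is.numeric(block))
    pf_stop("`block` must be a numeric matrix")
  if (any(abs(angles_deg) >= 90))
    pf_stop("angles must lie strictly inside (-90, 90) degrees")
  radon_projection_variance(block, as.numeric(angles_deg))
}

#' Radon-transform velocity estimate for one kymograph window
#'
#' Finds the streak angle maximizing the projection variance over a coarse
#' 1-degree grid on (-89, 89) degrees, then refines it by iterative grid
#' bracketing down to 0.001 degrees. The signed velocity is
#' `pixel_size * line_rate / 1000 * tan(angle)` mm/s. The separability
#' quality ratio is the maximum coarse-grid variance over its mean; values
#' near 1 indicate noise or motion-corrupted content, coherent streaks give
#' much larger values.
#'
#' @param window Numeric matrix block of a kymograph (rows = time), at
#'   least 32 lines, or a [kymograph()] (then calibration is taken from
#'   it). The global mean is subtracted internally.
#' @param line_rate,pixel_size Calibration (Hz; um/pixel); required when
#'   `window` is a bare matrix.
#' @param coarse_step Coarse grid spacing, degrees.
#' @param max_angle Largest candidate magnitude, degrees; an optimum within
#'   `coarse_step` of it is reported unresolvable (flow too fast for the
#'   line rate).
#' @param refine_to Final angular resolution, degrees.
#' @return A list of class `"radon_velocity"`: `velocity` (mm/s, `NA` when
#'   not `"ok"`), `theta_deg`, `separability`, `status` (`"ok"`,
#'   `"unresolvable"` or `"flat"`).
#' @examples
#' ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 128))
#' radon_window_velocity(ky)
#' @export
radon_window_velocity <- function(window, line_rate = NULL, pixel_size = NULL,
                                  coarse_step = 1, max_angle = 89,
                                  refine_to = 0.001) {
  if (inherits(window, "kymograph")) {
    line_rate <- line_rate %||% window$line_rate
    pixel_size <- pixel_size %||% window$pixel_size
    window <- window$image
  }
  if (is.null(line_rate) || is.null(pixel_size))
    pf_stop("line_rate and pixel_size are required with a matrix block")
  if (nrow(window) < 32L)
    pf_stop("Radon window needs at least 32 scan lines", "data")
  b <- window - mean(window)
  if (sd(b) == 0)
    return(structure(list(velocity = NA_real_, theta_deg = NA_real_,
                          separability = NA_real_, status = "flat"),
                     class = "radon_velocity"))
  coarse <- seq(-max_angle, max_angle, by = coarse_step)
  v <- coarse_scan_cached(b, coarse, max_angle, coarse_step)
  if (max(v) <= 0)
    return(structure(list(velocity = NA_real_, theta_deg = NA_real_,
                          separability = NA_real_, status = "flat"),
                     class = "radon_velocity"))
  separability <- max(v) / mean(v)
  theta <- coarse[which.max(v)]
  # bracketed refinement with generous overlapping spans (5x the new step
  # on each side): the objective carries fine-scale lattice ripple, so each
  # stage must sweep well beyond the previous step to land on the same
  # optimum an exhaustive fine grid would find
  step <- coarse_step
  while (step > 10 * refine_to) {
    span <- step
    step <- max(step / 10, 10 * refine_to)
    grid <- seq(theta - span, theta + span, by = step)
    grid <- grid[abs(grid) < 89.999]
    vv <- radon_angle_scan(b, grid)
    theta <- grid[which.max(vv)]
  }
  grid <- seq(theta - 50 * refine_to, theta + 50 * refine_to, by = refine_to)
  grid <- grid[abs(grid) < 89.999]
  vv <- radon_angle_scan(b, grid)
  theta <- grid[which.max(vv)]
  if (abs(theta) >= max_angle)
    return(structure(list(velocity = NA_real_, theta_deg = theta,
                          separability = separability,
                          status = "unresolvable"),
                     class = "radon_velocity"))
  vel <- pixel_size * line_rate / 1000 * tan(theta * pi / 180)
  structure(list(velocity = vel, theta_deg = theta,
                 separability = separability, status = "ok"),
            class = "radon_velocity")
}

#' @export
print.radon_velocity <- function(x, ...) {
  cat(sprintf("radon window: status %s, velocity %.4g mm/s (theta %.3f deg, separability %.2f)\n",
              x$status, x$velocity, x$theta_deg, x$separability))
  invisible(x)
}

#' Cross-correlation velocity estimate for one kymograph window
#'
#' For every pair of scan lines separated by `line_lag`, the mean-subtracted
#' lines are cross-correlated; the correlograms (mean product per
#' overlapping sample) are averaged across pairs and the peak lag located
#' with parabolic sub-pixel interpolation. This resolves fast flow whose
#' streaks are nearly horizontal and thus at the angular resolution limit of
#' the Radon method. Velocity is
#' `peak_shift * pixel_size * line_rate / (1000 * line_lag)` mm/s.
#'
#' @param window Numeric matrix block (rows = time) or a [kymograph()];
#'   needs at least `line_lag + 8` lines.
#' @inheritParams radon_window_velocity
#' @param line_lag Row separation between correlated line pairs.
#' @param min_peak_corr Floor on the normalized peak correlation below which
#'   the window is rejected as incoherent.
#' @param max_shift Largest shift searched, pixels; default half the window
#'   width. A peak on the search boundary is reported unresolvable.
#' @return A list of class `"correlation_velocity"`: `velocity`,
#'   `peak_shift_px`, `peak_corr`, `status` (`"ok"`, `"unresolvable"`,
#'   `"rejected"`).
#' @export
correlation_window_velocity <- function(window, line_rate = NULL,
                                        pixel_size = NULL, line_lag = 1L,
                                        min_peak_corr = 0.25,
                                        max_shift = NULL) {
  if (inherits(window, "kymograph")) {
    line_rate <- line_rate %||% window$line_rate
    pixel_size <- pixel_size %||% window$pixel_size
    window <- window$image
  }
  if (is.null(line_rate) || is.null(pixel_size))
    pf_stop("line_rate and pixel_size are required with a matrix block")
  nr <- nrow(window); nc <- ncol(window)
  if (nr < line_lag + 8L)
    pf_stop("correlation window needs at least line_lag + 8 lines", "data")
  L <- as.integer(max_shift %||% floor(nc / 2))
  rows <- sweep(window, 1, rowMeans(window))
  A <- rows[seq_len(nr - line_lag), , drop = FALSE]
  B <- rows[(1L + line_lag):nr, , drop = FALSE]
  pa <- mean(A^2); pb <- mean(B^2)
  if (pa == 0 || pb == 0)
    return(structure(list(velocity = NA_real_, peak_shift_px = NA_real_,
                          peak_corr = NA_real_, status = "rejected"),
                     class = "correlation_velocity"))
  lags <- seq.int(-L, L)
  cg <- vapply(lags, function(s) {
    if (s >= 0) mean(A[, seq_len(nc - s), drop = FALSE] *
                       B[, (1L + s):nc, drop = FALSE])
    else mean(A[, (1L - s):nc, drop = FALSE] *
                B[, seq_len(nc + s), drop = FALSE])
  }, numeric(1))
  cg <- cg / sqrt(pa * pb)
  ipk <- which.max(cg)
  if (ipk == 1L || ipk == length(lags))
    return(structure(list(velocity = NA_real_,
                          peak_shift_px = lags[ipk],
                          peak_corr = cg[ipk], status = "unresolvable"),
                     class = "correlation_velocity"))
  if (cg[ipk] < min_peak_corr)
    return(structure(list(velocity = NA_real_, peak_shift_px = lags[ipk],
                          peak_corr = cg[ipk], status = "rejected"),
                     class = "correlation_velocity"))
  denom <- cg[ipk - 1L] - 2 * cg[ipk] + cg[ipk + 1L]
  delta <- if (denom < 0) 0.5 * (cg[ipk - 1L] - cg[ipk + 1L]) / denom else 0
  shift <- lags[ipk] + delta
  vel <- shift * pixel_size * line_rate / (1000 * line_lag)
  structure(list(velocity = vel, peak_shift_px = shift,
                 peak_corr = cg[ipk], status = "ok"),
            class = "correlation_velocity")
}

#' @export
print.correlation_velocity <- function(x, ...) {
  cat(sprintf("correlation window: status %s, velocity %.4g mm/s (shift %.2f px, peak corr %.2f)\n",
              x$status, x$velocity, x$peak_shift_px, x$peak_corr))
  invisible(x)
}

#' Windowed centerline velocity estimate for a whole kymograph
#'
#' Slides a window across the scan lines and estimates each window's
#' velocity by the Radon streak-angle method, falling back to the
#' cross-correlation method when the Radon angle is at its resolvability
#' limit (flow too fast for the line rate). Before the angle search, each
#' window is mean-subtracted per column to suppress static stripes such as
#' vessel-wall shadows. Windows whose separability falls below
#' `sep_threshold` are rejected as noise or movement artifact; the aggregate
#' velocity is the median (or mean) over accepted windows. The accepted
#' duration is compared against the 40 s representative-flow quality
#' standard and flagged when shorter.
#'
#' @param kymo A [kymograph()].
#' @param window Window length in scan lines.
#' @param hop Hop between successive window starts, lines.
#' @param sep_threshold Separability acceptance threshold.
#' @param min_duration_s Accepted-duration quality standard, seconds.
#' @param aggregate `"median"` (robust default) or `"mean"`.
#' @param line_lag Line lag for the correlation fallback.
#' @param min_peak_corr Correlation-peak floor for the fallback.
#' @return An object of class `"velocity_estimate"`: `velocity` (mm/s,
#'   aggregate over accepted windows), `per_window` data frame
#'   (`start_line`, `velocity_mm_s`, `separability`, `method`, `accepted`),
#'   `accepted_duration` (s), `below_standard` flag, and `method`
#'   (the method used by the majority of accepted windows).
#' @examples
#' ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 1024))
#' estimate_velocity(ky)
#' @export
estimate_velocity <- function(kymo, window = 128L, hop = 64L,
                              sep_threshold = 3, min_duration_s = 40,
                              aggregate = c("median", "mean"),
                              line_lag = 1L, min_peak_corr = 0.25) {
  aggregate <- match.arg(aggregate)
  if (!inherits(kymo, "kymograph"))
    pf_stop("`kymo` must be a kymograph object")
  img <- kymo$image
  nl <- nrow(img)
  if (nl < window) pf_stop("kymograph shorter than one window", "data")
  starts <- seq.int(1L, nl - window + 1L, by = hop)
  # static stripes (vessel-wall shadows) are constant over the whole scan;
  # subtracting the record-wide column mean removes them without
  # high-passing slow streaks the way a per-window column mean would
  colmu <- colMeans(img)
  res <- lapply(starts, function(s0) {
    block <- img[s0:(s0 + window - 1L), , drop = FALSE]
    block <- sweep(block, 2, colmu)
    r <- radon_window_velocity(block, kymo$line_rate, kymo$pixel_size)
    vel <- NA_real_; method <- "radon"
    if (r$status == "ok") {
      vel <- r$velocity
    } else if (r$status == "unresolvable") {
      cc <- correlation_window_velocity(block, kymo$line_rate,
                                        kymo$pixel_size, line_lag = line_lag,
                                        min_peak_corr = min_peak_corr)
      if (cc$status == "ok") { vel <- cc$velocity; method <- "correlation" }
    }
    data.frame(start_line = s0, velocity_mm_s = vel,
               separability = r$separability, method = method,
               accepted = is.finite(vel) && !is.na(r$separability) &&
                 r$separability >= sep_threshold,
               stringsAsFactors = FALSE)
  })
  per_window <- do.call(rbind, res)
  acc <- per_window$accepted
  if (!any(acc))
    pf_stop("no window passed quality control; no velocity estimate",
            "compute")
  vels <- per_window$velocity_mm_s[acc]
  vel <- if (aggregate == "median") median(vels) else mean(vels)
  accepted_duration <- sum(acc) * hop / kymo$line_rate
  methods_acc <- per_window$method[acc]
  structure(list(velocity = vel, per_window = per_window,
                 accepted_duration = accepted_duration,
                 below_standard = accepted_duration < min_duration_s,
                 method = names(which.max(table(methods_acc)))),
            class = "velocity_estimate")
}
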