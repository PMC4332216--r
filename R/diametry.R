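#' Full-width-at-half-maximum lumen diameter from an intensity profile
#'
#' Measures the diameter of a plasma-labelled vessel (bright lumen on dark
#' background) from a 1-D intensity profile sampled perpendicular to the
#' vessel axis. The profile is Gaussian-smoothed, a local baseline is taken
#' as the average of the medians of the outer samples on each side, and the
#' diameter is the distance between the two linearly interpolated crossings
#' of the half-maximum level that bound the contiguous above-half-max run
#' containing the global peak. Anchoring on the peak's own run makes the
#' measurement deterministic when a second vessel intrudes into the profile.
#'
#' @param profile Numeric intensity vector (length >= 8) or a
#'   [generate_profile()] / [extract_profile()] object.
#' @param pixel_size Sample spacing, um; taken from the profile object when
#'   available.
#' @param smooth_sd Gaussian smoothing sd in samples; 0 disables smoothing.
#' @param threshold_frac Crossing level as a fraction of the baseline-to-peak
#'   contrast (0.5 = half maximum).
#' @param min_contrast Minimum peak-minus-baseline contrast, in the
#'   profile's intensity units, below which no vessel is declared.
#' @param baseline_frac Fraction of samples on each side used for the local
#'   baseline.
#' @return An object of class `"diameter_estimate"`: `diameter` (um),
#'   `half_max_level`, `baseline`, `peak`, `crossings` (the two crossing
#'   positions, um, on the axis `sample_index * pixel_size`).
#' @examples
#' pr <- generate_profile(20, pixel_size = 0.5, shape = "gaussian")
#' fwhm_diameter(pr)
#' @export
fwhm_diameter <- function(profile, pixel_size = NULL, smooth_sd = 1,
                          threshold_frac = 0.5, min_contrast = 0.05,
                          baseline_frac = 0.1) {
  if (inherits(profile, "vessel_profile")) {
    pixel_size <- pixel_size %||% profile$pixel_size
    profile <- profile$intensity
  }
  if (is.null(pixel_size) || pixel_size <= 0)
    pf_stop("`pixel_size` (um/sample) is required and must be positive")
  y <- as.numeric(profile)
  n <- length(y)
  if (n < 8L) pf_stop("profile needs at least 8 samples", "data")
  sm <- gaussian_smooth(y, smooth_sd)
  nb <- max(2L, round(baseline_frac * n))
  # baseline from the raw outer samples: medians of smoothed tails are
  # noisier (correlated samples) and no more robust here
  baseline <- median(c(head(y, nb), tail(y, nb)))
  ipk <- which.max(sm)
  peak <- sm[ipk]
  if (peak - baseline < min_contrast)
    pf_stop(sprintf("peak-baseline contrast %.3g below floor %.3g: no vessel",
                    peak - baseline, min_contrast), "data")
  # refine the peak level as the vertex of a quadratic fitted over the top
  # band (>= 75% contrast): the raw maximum of a noisy profile is biased
  # upward by max-selection, which coherently narrows the half-max width
  tb <- sm >= baseline + 0.75 * (peak - baseline)
  tl <- ipk; while (tl > 1L && tb[tl - 1L]) tl <- tl - 1L
  tr <- ipk; while (tr < n && tb[tr + 1L]) tr <- tr + 1L
  if (tr - tl >= 4L) {
    w <- tl:tr
    cf <- coef(lm(sm[w] ~ w + I(w^2)))
    if (!anyNA(cf) && cf[3] < 0) {
      vertex <- unname(cf[1] - cf[2]^2 / (4 * cf[3]))
      if (abs(vertex - peak) < 0.5 * (peak - baseline)) peak <- vertex
    }
  }
  half <- baseline + threshold_frac * (peak - baseline)
  above <- sm >= half
  il <- ipk; while (il > 1L && above[il - 1L]) il <- il - 1L
  ir <- ipk; while (ir < n && above[ir + 1L]) ir <- ir + 1L
  if (il == 1L || ir == n)
    pf_stop("above-half-max run touches the profile end: profile too short",
            "data")
  x <- seq_len(n) * pixel_size
  fl <- (half - sm[il - 1L]) / (sm[il] - sm[il - 1L])
  xl <- x[il - 1L] + fl * pixel_size
  fr <- (sm[ir] - half) / (sm[ir] - sm[ir + 1L])
  xr <- x[ir] + fr * pixel_size
  structure(list(diameter = xr - xl, half_max_level = half,
                 baseline = baseline, peak = peak,
                 crossings = c(xl, xr)),
            class = "diameter_estimate")
}

# Gaussian smoothing with replicate-padded edges
gaussian_smooth <- function(y, sd_px) {
  if (sd_px <= 0) return(y)
  r <- max(1L, ceiling(4 * sd_px))
  k <- exp(-((-r:r)^2) / (2 * sd_px^2)); k <- k / sum(k)
  n <- length(y)
  yp <- c(rep(y[1], r), y, rep(y[n], r))
  as.numeric(stats::filter(yp, k, sides = 2))[(r + 1L):(r + n)]
}

#' Percent diameter change between consecutive sessions
#'
#' `100 * (d_next - d_t) / d_t`, the quantity regressed on log10 shear rate
#' in the remodeling analysis. Vectorized.
#'
#' @param d_t Diameter at day t, um (> 0).
#' @param d_next Diameter at day t + 1, um.
#' @return Percent change (may exceed 100, the outlier-exclusion threshold
#'   of [fit_remodeling()]).
#' @export
percent_diameter_change <- function(d_t, d_next) {
  if (any(d_t <= 0, na.rm = TRUE))
    pf_stop("d_t must be positive", "data")
  100 * (d_next - d_t) / d_t
}

#' Sample an intensity profile along a straight chord of an image
#'
#' Thin utility extracting the 1-D profile used by [fwhm_diameter()] from a
#' frame image, by sampling a user-drawn line with bilinear interpolation at
#' one-pixel steps.
#'
#' @param image Numeric matrix (rows = y, columns = x), e.g. a vessel frame.
#' @param x0,y0,x1,y1 Chord endpoints in pixel coordinates (column, row).
#' @param pixel_size Image pixel size, um/pixel.
#' @param step Sampling step along the chord, pixels.
#' @return A `"vessel_profile"` object whose `pixel_size` is the sample
#'   spacing in um (`step * pixel_size`).
#' @export
extract_profile <- function(image, x0, y0, x1, y1, pixel_size, step = 1) {
  if (!is.matrix(image)) pf_stop("`image` must be a matrix")
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) pf_stop("chord endpoints coincide", "data")
  tt <- seq(0, len, by = step) / len
  xs <- x0 + tt * (x1 - x0)
  ys <- y0 + tt * (y1 - y0)
  nr <- nrow(image); nc <- ncol(image)
  xs <- pmin(pmax(xs, 1), nc); ys <- pmin(pmax(ys, 1), nr)
  xf <- pmin(floor(xs), nc - 1L); yf <- pmin(floor(ys), nr - 1L)
  dx <- xs - xf; dy <- ys - yf
  v <- image[cbind(yf, xf)] * (1 - dx) * (1 - dy) +
    image[cbind(yf, xf + 1L)] * dx * (1 - dy) +
    image[cbind(yf + 1L, xf)] * (1 - dx) * dy +
    image[cbind(yf + 1L, xf + 1L)] * dx * dy
  structure(list(intensity = as.numeric(v), pixel_size = step * pixel_size,
                 truth = NULL),
            class = "vessel_profile")
}
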