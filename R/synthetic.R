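#' Ground-truth description of a synthetic kymograph
#'
#' Collects the acquisition and scene parameters from which
#' [generate_kymograph()] renders a linescan image. Red blood cells are
#' modelled as dark streaks (the labelled plasma is bright, unlabelled cells
#' exclude the dye) entering the upstream edge of the scanned field as a
#' Poisson process and advancing at the commanded velocity.
#'
#' @param velocity Commanded centerline velocity in mm/s, signed; positive
#'   velocity moves streaks toward increasing spatial coordinate.
#' @param line_rate Scan line rate in Hz (default 2000, a typical two-photon
#'   linescan rate).
#' @param pixel_size Spatial pixel size, um/pixel.
#' @param n_lines,n_pixels Image size: number of scan lines (time) and
#'   spatial pixels. Both at least 16.
#' @param streak_width Full width at half maximum of a cell's dark
#'   cross-profile, um (default 6, the scale of a mouse red blood cell).
#' @param streak_rate Cells entering the field per second. `NULL` (default)
#'   auto-selects the rate so that on average `mean_streaks_in_field` cells
#'   are in the field at once; for zero velocity the rate is 0 and the field
#'   is seeded with stationary cells instead.
#' @param contrast Fractional intensity dip at a streak centre (0-1).
#' @param background Plasma background intensity.
#' @param noise_sd Standard deviation of additive Gaussian noise, intensity
#'   units.
#' @param artifact_windows List of `c(start_line, end_line)` intervals whose
#'   lines are corrupted by motion: each line is independently displaced by a
#'   uniform spatial jitter of up to a quarter of the field width, which
#'   decorrelates the streak pattern locally.
#' @param mean_streaks_in_field Target mean number of cells concurrently in
#'   the field when `streak_rate` is auto-selected.
#' @param seed Integer seed; generation is fully deterministic given the
#'   truth object.
#'
#' @return An object of class `"kymograph_truth"`.
#' @export
kymograph_truth <- function(velocity,
                            line_rate = 2000,
                            pixel_size = 0.5,
                            n_lines = 4000L,
                            n_pixels = 128L,
                            streak_width = 6,
                            streak_rate = NULL,
                            contrast = 0.6,
                            background = 1,
                            noise_sd = 0,
                            artifact_windows = list(),
                            mean_streaks_in_field = 4,
                            seed = 1L) {
  if (line_rate <= 0 || pixel_size <= 0)
    pf_stop("line_rate and pixel_size must be positive")
  if (n_lines < 16L || n_pixels < 16L)
    pf_stop("n_lines and n_pixels must be at least 16")
  if (streak_width <= 0) pf_stop("streak_width must be positive")
  if (contrast <= 0 || contrast > 1) pf_stop("contrast must be in (0, 1]")
  shift <- velocity * 1000 / (line_rate * pixel_size)  # pixels per line
  if (abs(shift) >= n_pixels / 2)
    pf_stop(sprintf(paste0("commanded shift %.2f px/line >= n_pixels/2 = %g: ",
                           "streaks are unrecoverably aliased; raise line_rate"),
                    shift, n_pixels / 2), "data")
  if (is.null(streak_rate))
    streak_rate <- mean_streaks_in_field * abs(shift) * line_rate / n_pixels
  if (streak_rate < 0) pf_stop("streak_rate must be nonnegative")
  structure(list(velocity = velocity, line_rate = line_rate,
                 pixel_size = pixel_size, n_lines = as.integer(n_lines),
                 n_pixels = as.integer(n_pixels), streak_width = streak_width,
                 streak_rate = streak_rate, contrast = contrast,
                 background = background, noise_sd = noise_sd,
                 artifact_windows = artifact_windows,
                 mean_streaks_in_field = mean_streaks_in_field,
                 pixel_shift_per_line = shift, seed = as.integer(seed)),
            class = "kymograph_truth")
}

# pixel indices and transmission factors of one dark streak (rows = time).
# c0: spatial centre (pixels) at fractional line t0; s >= 0 pixels/line.
streak_pixels <- function(nl, np, c0, t0, s, sig_px, half_width, contrast) {
  tmax <- if (s > 0) floor(t0 + (np + half_width - c0) / s) else nl
  tlo <- max(1, ceiling(t0))
  if (tmax < tlo) return(NULL)
  rows <- seq.int(tlo, min(nl, tmax))
  cen <- c0 + s * (rows - t0)
  off <- seq.int(-half_width, half_width)
  J <- rep(round(cen), times = length(off)) + rep(off, each = length(rows))
  Tt <- rep(rows, times = length(off))
  Cc <- rep(cen, times = length(off))
  keep <- J >= 1 & J <= np
  if (!any(keep)) return(NULL)
  list(idx = cbind(Tt[keep], J[keep]),
       fac = 1 - contrast * exp(-((J[keep] - Cc[keep])^2) / (2 * sig_px^2)))
}

#' Render a synthetic linescan kymograph with known velocity
#'
#' Produces a space-time image of dark red-blood-cell streaks on a bright
#' plasma background. Streaks have a Gaussian cross-profile of FWHM
#' `streak_width` and advance `velocity * 1000 / (line_rate * pixel_size)`
#' pixels per scan line. The image for a negative velocity is the exact
#' spatial mirror of the image for the same speed and seed. Motion-artifact
#' intervals are rendered by jittering each affected line sideways by a
#' uniform random fraction of up to a quarter of the field width.
#'
#' @param truth A [kymograph_truth()] object.
#' @return A [kymograph()] with the truth attached as `$truth`.
#' @examples
#' ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 256))
#' dim(ky$image)
#' @export
generate_kymograph <- function(truth) {
  if (!inherits(truth, "kymograph_truth"))
    pf_stop("`truth` must be a kymograph_truth object")
  np <- truth$n_pixels; nl <- truth$n_lines
  s <- abs(truth$pixel_shift_per_line)
  sig_px <- truth$streak_width / FWHM_PER_SD / truth$pixel_size
  w <- max(1L, ceiling(4 * sig_px))
  img <- with_seed(truth$seed, {
    # transmission field: each cell attenuates multiplicatively
    img <- matrix(truth$background, nl, np)
    # stationary seeding: cells already in the field at the first line
    n0 <- rpois(1L, truth$mean_streaks_in_field)
    x0 <- runif(n0, 1 - w, np + w)
    # Poisson arrivals at the upstream edge during the scan
    rate_per_line <- truth$streak_rate / truth$line_rate
    n_arr <- rpois(1L, rate_per_line * nl)
    t_arr <- if (n_arr > 0) sort(runif(n_arr, 1, nl)) else numeric()
    centres <- c(x0, rep(1 - w, n_arr))
    t0s <- c(rep(1, n0), t_arr)
    for (k in seq_along(centres)) {
      sp <- streak_pixels(nl, np, centres[k], t0s[k], s, sig_px, w,
                          truth$contrast)
      if (!is.null(sp)) img[sp$idx] <- img[sp$idx] * sp$fac
    }
    if (truth$noise_sd > 0)
      img <- img + matrix(rnorm(nl * np, 0, truth$noise_sd), nl, np)
    for (aw in truth$artifact_windows) {
      rows <- seq.int(max(1L, aw[1]), min(nl, aw[2]))
      jit <- round(runif(length(rows), -0.25, 0.25) * np)
      for (ii in seq_along(rows))
        img[rows[ii], ] <- circshift(img[rows[ii], ], jit[ii])
    }
    img
  })
  # negative commanded velocity: mirror the whole scene along space
  if (truth$pixel_shift_per_line < 0) img <- img[, np:1, drop = FALSE]
  kymograph(img, truth$line_rate, truth$pixel_size, truth = truth)
}

#' Synthetic vessel cross-section intensity profile of known diameter
#'
#' Generates a 1-D profile of a plasma-labelled vessel lumen (bright) on a
#' dark background, with the true full width at half maximum equal to
#' `diameter` by construction: a top-hat of width `diameter`, or a Gaussian
#' with sd `diameter / (2 sqrt(2 log 2))`. The lumen centre sits midway
#' between two samples so discretization is representative of real chords.
#'
#' @param diameter True lumen diameter, um. Must exceed `2 * pixel_size`.
#' @param pixel_size Sample spacing, um.
#' @param shape `"tophat"` or `"gaussian"`.
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param seed Integer seed for the noise.
#' @param n_pixels Profile length; default covers three diameters so the
#'   outer tails are pure background.
#' @param background,peak Background and lumen-centre intensities.
#'
#' @return An object of class `"vessel_profile"`: list with `intensity`,
#'   `pixel_size`, and a `truth` list.
#' @seealso [fwhm_diameter()]
#' @export
generate_profile <- function(diameter, pixel_size = 0.5,
                             shape = c("tophat", "gaussian"),
                             noise_sd = 0, seed = 1L, n_pixels = NULL,
                             background = 0.1, peak = 1) {
  shape <- match.arg(shape)
  if (diameter <= 2 * pixel_size)
    pf_stop(sprintf("diameter %g um is not resolvable at %g um/pixel",
                    diameter, pixel_size), "data")
  n_pixels <- as.integer(n_pixels %||% max(64L, ceiling(3 * diameter / pixel_size)))
  x <- seq_len(n_pixels) * pixel_size
  centre <- (floor(n_pixels / 2) + 0.5) * pixel_size
  inten <- if (shape == "tophat") {
    background + (peak - background) * (abs(x - centre) <= diameter / 2)
  } else {
    sig <- diameter / FWHM_PER_SD
    background + (peak - background) * exp(-((x - centre)^2) / (2 * sig^2))
  }
  if (noise_sd > 0)
    inten <- with_seed(seed, inten + rnorm(n_pixels, 0, noise_sd))
  structure(list(intensity = as.numeric(inten), pixel_size = pixel_size,
                 truth = list(diameter = diameter, shape = shape,
                              centre = centre, noise_sd = noise_sd,
                              seed = as.integer(seed))),
            class = "vessel_profile")
}

#' Ground-truth description of a longitudinal vessel cohort
#'
#' Parameters for [generate_cohort()]: a set of vessels whose next-day
#' percent diameter change follows a known linear law in log10 wall shear
#' rate, `pct = slope * log10(shear) + intercept + N(0, noise_sd^2)`.
#' Defaults reproduce the remodeling law fitted to pial venules,
#' `slope = 15.4` %/log10(1/s) and `intercept = -40.9` %.
#'
#' @param n_vessels Number of vessels (>= 2).
#' @param slope,intercept Remodeling law coefficients (% per log10(1/s), %).
#' @param noise_sd Vessel-to-vessel sd of the percent change around the
#'   law, %.
#' @param diameter_range,velocity_range Day-1 draw ranges (um; mm/s), both
#'   strictly positive; draws are log-uniform so shear rate spans orders of
#'   magnitude, as in the study population.
#' @param age_days Optional integer vector of postnatal ages at day 1, one
#'   per vessel; default draws uniformly from P2-P11.
#' @param n_days Number of consecutive imaging days to simulate (default 2;
#'   each extra day applies the law again with a freshly drawn velocity).
#' @param vd_rho Optional Gaussian-copula correlation between day-1
#'   velocity and diameter ranks; `NULL` (default) draws them independently.
#' @param seed Integer seed.
#' @return An object of class `"cohort_truth"`.
#' @export
cohort_truth <- function(n_vessels = 50L, slope = 15.4, intercept = -40.9,
                         noise_sd = 0, diameter_range = c(10, 100),
                         velocity_range = c(0.2, 10), age_days = NULL,
                         n_days = 2L, vd_rho = NULL, seed = 1L) {
  if (n_vessels < 2L) pf_stop("n_vessels must be at least 2")
  if (any(diameter_range <= 0) || any(velocity_range <= 0))
    pf_stop("diameter_range and velocity_range must be strictly positive")
  if (n_days < 2L) pf_stop("n_days must be at least 2")
  if (!is.null(vd_rho) && abs(vd_rho) >= 1)
    pf_stop("vd_rho must be in (-1, 1)")
  if (!is.null(age_days) && length(age_days) != n_vessels)
    pf_stop("age_days must have one entry per vessel")
  structure(list(n_vessels = as.integer(n_vessels), slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 diameter_range = sort(diameter_range),
                 velocity_range = sort(velocity_range),
                 age_days = age_days, n_days = as.integer(n_days),
                 vd_rho = vd_rho, seed = as.integer(seed)),
            class = "cohort_truth")
}

# log-uniform draw from quantiles u in [0,1]
qlogunif <- function(u, range) 10^(log10(range[1]) + u * diff(log10(range)))

#' Simulate a longitudinal cohort following a known remodeling law
#'
#' For each vessel, the day-1 diameter and velocity are drawn log-uniformly
#' over their ranges (optionally rank-correlated through a Gaussian copula);
#' the wall shear rate is `4 * v / D` (with v in um/s) and the next-day
#' diameter applies the percent change
#' `slope * log10(shear) + intercept + noise`. A vessel whose diameter
#' would become nonpositive is recorded as pruned (diameter `NA`) and
#' carried no further.
#'
#' @param truth A [cohort_truth()] object.
#' @return A list with two data frames: `observations` with columns
#'   `vessel_id, age_day, day, diameter_um, velocity_mm_s` (one row per
#'   vessel per day), and `truth` with per-transition columns `vessel_id,
#'   day, shear_rate_per_s, pct_change_true` where `shear_rate_per_s` is
#'   recomputed from the emitted velocity and diameter columns.
#' @examples
#' coh <- generate_cohort(cohort_truth(n_vessels = 5, noise_sd = 0))
#' head(coh$observations)
#' @export
generate_cohort <- function(truth) {
  if (!inherits(truth, "cohort_truth"))
    pf_stop("`truth` must be a cohort_truth object")
  n <- truth$n_vessels
  ids <- sprintf("v%03d", seq_len(n))
  with_seed(truth$seed, {
    ages <- truth$age_days %||% sample(2:11, n, replace = TRUE)
    # day-1 draws, optionally rank-correlated via a Gaussian copula
    if (is.null(truth$vd_rho)) {
      u_d <- runif(n); u_v <- runif(n)
    } else {
      z1 <- rnorm(n); z2 <- truth$vd_rho * z1 +
        sqrt(1 - truth$vd_rho^2) * rnorm(n)
      u_d <- pnorm(z1); u_v <- pnorm(z2)
    }
    D <- matrix(NA_real_, n, truth$n_days)
    V <- matrix(NA_real_, n, truth$n_days)
    D[, 1] <- qlogunif(u_d, truth$diameter_range)
    V[, 1] <- qlogunif(u_v, truth$velocity_range)
    tr <- vector("list", truth$n_days - 1L)
    for (d in seq_len(truth$n_days - 1L)) {
      alive <- !is.na(D[, d])
      sh <- ifelse(alive, shear_rate(V[, d], pmax(D[, d], 1e-12)), NA_real_)
      eps <- rnorm(n, 0, truth$noise_sd)
      pct <- truth$slope * log10(sh) + truth$intercept +
        if (truth$noise_sd > 0) eps else 0
      nd <- D[, d] * (1 + pct / 100)
      nd[!alive | nd <= 0] <- NA_real_   # pruned to invisibility
      D[, d + 1L] <- nd
      V[, d + 1L] <- ifelse(is.na(nd), NA_real_,
                            qlogunif(runif(n), truth$velocity_range))
      tr[[d]] <- data.frame(vessel_id = ids, day = d,
                            shear_rate_per_s = sh, pct_change_true = pct,
                            stringsAsFactors = FALSE)
    }
    obs <- data.frame(
      vessel_id = rep(ids, times = truth$n_days),
      age_day = rep(ages, times = truth$n_days) +
        rep(seq_len(truth$n_days) - 1L, each = n),
      day = rep(seq_len(truth$n_days), each = n),
      diameter_um = as.vector(D),
      velocity_mm_s = as.vector(V),
      stringsAsFactors = FALSE)
    obs <- obs[order(obs$vessel_id, obs$day), , drop = FALSE]
    rownames(obs) <- NULL
    list(observations = obs, truth = do.call(rbind, tr))
  })
}
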