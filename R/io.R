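#' Write a kymograph as a 32-bit TIFF with a YAML calibration sidecar
#'
#' Intensities are affinely mapped to \[0, 1\] for storage (the TIFF writer
#' clips outside that range) and the original range is recorded in the
#' sidecar, so reading restores the image to 32-bit float precision.
#' Calibration always travels in the sidecar, never in TIFF tags, whose
#' conventions vary across acquisition software.
#'
#' @param kymo A [kymograph()].
#' @param path Output TIFF path.
#' @param sidecar Sidecar YAML path; default `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(kymo, path,
                                 sidecar = paste0(path, ".yaml")) {
  if (!inherits(kymo, "kymograph")) pf_stop("`kymo` must be a kymograph")
  img <- kymo$image
  lo <- min(img); hi <- max(img)
  norm <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  meta <- list(line_rate_hz = kymo$line_rate,
               pixel_size_um = kymo$pixel_size,
               intensity_min = lo, intensity_max = hi)
  if (!is.null(kymo$truth)) {
    tr <- kymo$truth
    meta$truth <- list(velocity_mm_s = tr$velocity,
                       streak_width_um = tr$streak_width,
                       streak_rate_per_s = tr$streak_rate,
                       noise_sd = tr$noise_sd, contrast = tr$contrast,
                       seed = tr$seed)
  }
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read a kymograph from a TIFF plus calibration
#'
#' Accepts 8/16-bit and 32-bit float grayscale TIFFs; multi-page files are
#' concatenated row-wise in page order (pages are successive blocks of scan
#' lines). Calibration must be supplied by the YAML sidecar or the explicit
#' arguments (which take precedence); it is never inferred from TIFF tags.
#'
#' @param path TIFF path.
#' @param sidecar Sidecar YAML path; default `<path>.yaml` when it exists.
#' @param line_rate_hz,pixel_size_um Explicit calibration overrides.
#' @return A [kymograph()].
#' @export
read_kymograph_tiff <- function(path, sidecar = NULL,
                                line_rate_hz = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) pf_stop(paste("no such file:", path), "data")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      pf_stop(paste("cannot read TIFF:", conditionMessage(e)),
                              "data"))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) == 3L, logical(1))))
    pf_stop("RGB/multi-channel TIFF not supported: supply grayscale", "data")
  img <- do.call(rbind, pages)
  meta <- list()
  sidecar <- sidecar %||%
    (if (file.exists(paste0(path, ".yaml"))) paste0(path, ".yaml") else NULL)
  if (!is.null(sidecar)) {
    if (!file.exists(sidecar))
      pf_stop(paste("sidecar not found:", sidecar), "data")
    meta <- yaml::read_yaml(sidecar)
  }
  line_rate_hz <- line_rate_hz %||% meta$line_rate_hz
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(line_rate_hz))
    pf_stop("calibration missing: line_rate_hz (sidecar or argument)", "data")
  if (is.null(pixel_size_um))
    pf_stop("calibration missing: pixel_size_um (sidecar or argument)", "data")
  if (!is.null(meta$intensity_min) && !is.null(meta$intensity_max))
    img <- meta$intensity_min +
      img * (meta$intensity_max - meta$intensity_min)
  kymograph(img, line_rate_hz, pixel_size_um)
}

#' Write / read an observation table as CSV
#'
#' Column names carry their units (`diameter_um`, `velocity_mm_s`,
#' `shear_rate_per_s`).
#'
#' @param observations Data frame of vessel-session observations.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_observations_csv <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) pf_stop(paste("no such file:", path), "data")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a study manifest
#'
#' The manifest lists one row per vessel-session: identifiers, the
#' kymograph TIFF, the diameter source (either a precomputed profile CSV
#' with an `intensity` column, or a frame TIFF plus a chord
#' `"x0,y0,x1,y1"`), and acquisition calibration. Relative paths are
#' resolved against the manifest's own directory.
#'
#' @param manifest CSV path or data frame with columns `vessel_id,
#'   age_day, session_day, kymograph_path, line_rate_hz, pixel_size_um` and
#'   `profile_path` and/or (`frame_path`, `profile_chord`).
#' @return Validated data frame (paths resolved) with attribute `base_dir`.
#' @export
read_manifest <- function(manifest) {
  base_dir <- "."
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      pf_stop(paste("no such manifest:", manifest), "data")
    base_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(manifest)) pf_stop("manifest must be a CSV path or data frame")
  if (nrow(manifest) == 0L) pf_stop("empty manifest", "data")
  req <- c("vessel_id", "age_day", "session_day", "kymograph_path",
           "line_rate_hz", "pixel_size_um")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    pf_stop(paste("manifest lacks column(s):", paste(miss, collapse = ", ")),
            "data")
  if (!("profile_path" %in% names(manifest)) &&
      !all(c("frame_path", "profile_chord") %in% names(manifest)))
    pf_stop("manifest needs profile_path or frame_path + profile_chord",
            "data")
  if (anyDuplicated(paste(manifest$vessel_id, manifest$session_day)))
    pf_stop("duplicate (vessel_id, session_day) in manifest", "data")
  if (any(manifest$line_rate_hz <= 0) || any(manifest$pixel_size_um <= 0))
    pf_stop("calibration fields must be positive", "data")
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
                                p, file.path(base_dir, p))
  for (col in intersect(c("kymograph_path", "frame_path", "profile_path"),
                        names(manifest)))
    manifest[[col]] <- resolve(manifest[[col]])
  attr(manifest, "base_dir") <- base_dir
  manifest
}
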