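#' Run the full linescan-to-remodeling pipeline over a study manifest
#'
#' For every manifest row: read the kymograph, estimate the centerline
#' velocity ([estimate_velocity()]); obtain the cross-section profile (from
#' a profile CSV or by chord extraction from a frame TIFF) and measure the
#' FWHM diameter ([fwhm_diameter()]); assemble the observation with its
#' shear rate ([build_observation()]). Failing rows are logged and skipped;
#' the run aborts only if no row succeeds. Observations are then paired
#' across consecutive days ([pair_sessions()]), the remodeling regression
#' fitted with and without the >100% outlier rule ([fit_remodeling()]), and
#' the age-binned velocity-diameter correlations computed
#' ([age_bin_velocity_diameter()]).
#'
#' The pipeline is deterministic: identical manifest, files and
#' configuration give identical outputs (the run log's timestamp aside).
#'
#' @param manifest Manifest CSV path or data frame; see [read_manifest()].
#' @param out_dir Output directory, created if needed. Writes
#'   `observations.csv`, `remodeling_fit.json`, `per_window_qc.csv` and
#'   `run_log.json`. `NULL` writes nothing.
#' @inheritParams estimate_velocity
#' @inheritParams fit_remodeling
#' @param bins Age bins for [age_bin_velocity_diameter()].
#' @param verbose Log per-row outcomes with `message()`.
#' @return (Invisibly) a list: `observations`, `points`, `fit`
#'   (`remodeling_fit_pair` or `NULL`), `age_bins`, `log` (per-row status
#'   data frame), `per_window_qc`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL,
                         window = 128L, hop = 64L, sep_threshold = 3,
                         min_duration_s = 40, exclude_above = 100,
                         bins = list(c(2, 6), c(8, 12)), verbose = TRUE) {
  mf <- read_manifest(manifest)
  say <- function(...) if (verbose) message(sprintf(...))
  obs <- list(); qc <- list(); logs <- list()
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    status <- tryCatch({
      ky <- read_kymograph_tiff(row$kymograph_path,
                                line_rate_hz = row$line_rate_hz,
                                pixel_size_um = row$pixel_size_um)
      vel <- estimate_velocity(ky, window = window, hop = hop,
                               sep_threshold = sep_threshold,
                               min_duration_s = min_duration_s)
      prof <- pipeline_profile(row)
      dia <- fwhm_diameter(prof)
      ob <- build_observation(row$vessel_id, row$age_day, row$session_day,
                              dia, vel)
      obs[[length(obs) + 1L]] <- ob
      pw <- vel$per_window
      pw$vessel_id <- row$vessel_id
      pw$session_day <- row$session_day
      qc[[length(qc) + 1L]] <- pw
      sprintf("ok: v=%.3g mm/s D=%.3g um shear=%.3g /s",
              ob$velocity_mm_s, ob$diameter_um, ob$shear_rate_per_s)
    }, pialflow_error = function(e) paste("skipped:", conditionMessage(e)),
       error = function(e) paste("skipped:", conditionMessage(e)))
    say("[%s day %s] %s", row$vessel_id, row$session_day, status)
    logs[[i]] <- data.frame(vessel_id = row$vessel_id,
                            session_day = row$session_day,
                            status = status, stringsAsFactors = FALSE)
  }
  if (!length(obs))
    pf_stop("no manifest row produced an observation", "compute")
  observations <- do.call(rbind, obs)
  per_window_qc <- do.call(rbind, qc)
  points <- pair_sessions(observations)
  fit <- tryCatch(fit_remodeling(points, exclude_above = exclude_above),
                  pialflow_error = function(e) {
                    say("remodeling fit unavailable: %s", conditionMessage(e))
                    NULL
                  })
  age_bins <- age_bin_velocity_diameter(observations, bins = bins)
  log_df <- do.call(rbind, logs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_observations_csv(observations,
                           file.path(out_dir, "observations.csv"))
    write.csv(per_window_qc, file.path(out_dir, "per_window_qc.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(fit = if (is.null(fit)) NULL else fit_pair_as_list(fit),
           age_bins = age_bins),
      file.path(out_dir, "remodeling_fit.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(
      list(package = "pialflow",
           version = as.character(packageVersion("pialflow")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           config = list(window = window, hop = hop,
                         sep_threshold = sep_threshold,
                         min_duration_s = min_duration_s,
                         exclude_above = exclude_above, bins = bins),
           rows = log_df),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(observations = observations, points = points, fit = fit,
                 age_bins = age_bins, log = log_df,
                 per_window_qc = per_window_qc))
}

# diameter source for one manifest row: profile CSV, or frame + chord
pipeline_profile <- function(row) {
  has <- function(col) col %in% names(row) && !is.na(row[[col]]) &&
    nzchar(row[[col]])
  if (has("profile_path")) {
    pr <- read.csv(row$profile_path, stringsAsFactors = FALSE)
    if (!"intensity" %in% names(pr))
      pf_stop(paste("profile CSV lacks `intensity`:", row$profile_path),
              "data")
    ps <- if ("pixel_size_um" %in% names(pr)) pr$pixel_size_um[1]
          else row$pixel_size_um
    return(structure(list(intensity = pr$intensity, pixel_size = ps,
                          truth = NULL), class = "vessel_profile"))
  }
  if (has("frame_path") && has("profile_chord")) {
    frame <- tiff::readTIFF(row$frame_path)
    if (length(dim(frame)) == 3L)
      pf_stop("RGB frame TIFF not supported", "data")
    xy <- as.numeric(strsplit(row$profile_chord, ",")[[1]])
    if (length(xy) != 4L || anyNA(xy))
      pf_stop(paste("bad profile_chord:", row$profile_chord), "data")
    return(extract_profile(frame, xy[1], xy[2], xy[3], xy[4],
                           row$pixel_size_um))
  }
  pf_stop("row has neither profile_path nor frame_path + profile_chord",
          "data")
}

# JSON-serializable view of a remodeling_fit_pair (drops the lm objects)
fit_pair_as_list <- function(fit) {
  one <- function(f) list(slope = f$slope, intercept = f$intercept,
                          r_squared = f$r_squared, p_value = f$p_value,
                          n_used = f$n_used, n_excluded = f$n_excluded,
                          excluded_ids = f$excluded_ids)
  list(with_exclusion = one(fit$with_exclusion),
       without_exclusion = one(fit$without_exclusion),
       exclude_above = fit$exclude_above)
}
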