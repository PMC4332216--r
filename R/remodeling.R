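#' Pair longitudinal observations into consecutive-day remodeling points
#'
#' Builds the (x, y) points of the remodeling regression: for every vessel
#' observed on two consecutive session days with a usable shear rate on the
#' first day and a diameter on both, one point with
#' `log10_shear = log10(shear rate at day t)` and
#' `pct_change = 100 * (D_{t+1} - D_t) / D_t`. Pairs missing either
#' ingredient are skipped and recorded, with a reason, in the `"skipped"`
#' attribute of the result. Only lag-1 pairs are formed; the analysis does
#' not pool longer lags.
#'
#' @param observations Data frame with columns `vessel_id, session_day,
#'   diameter_um, velocity_mm_s` and optionally `shear_rate_per_s` (computed
#'   from velocity and diameter when absent). `(vessel_id, session_day)`
#'   must be unique.
#' @return Data frame of class `"remodeling_points"` with columns
#'   `vessel_id, session_day, log10_shear, pct_change`, and attribute
#'   `skipped` (data frame `vessel_id, session_day, reason`).
#' @export
pair_sessions <- function(observations) {
  req <- c("vessel_id", "session_day", "diameter_um", "velocity_mm_s")
  miss <- setdiff(req, names(observations))
  # accept the synthetic cohort's `day` column as the session index
  if ("session_day" %in% miss && "day" %in% names(observations)) {
    observations$session_day <- observations$day
    miss <- setdiff(miss, "session_day")
  }
  if (length(miss))
    pf_stop(paste("observations lack column(s):",
                  paste(miss, collapse = ", ")), "data")
  key <- paste(observations$vessel_id, observations$session_day, sep = "\r")
  if (anyDuplicated(key))
    pf_stop("duplicate (vessel_id, session_day) rows in observations", "data")
  if (!"shear_rate_per_s" %in% names(observations)) {
    ok <- !is.na(observations$velocity_mm_s) &
      !is.na(observations$diameter_um) & observations$diameter_um > 0
    observations$shear_rate_per_s <- NA_real_
    observations$shear_rate_per_s[ok] <-
      shear_rate(observations$velocity_mm_s[ok], observations$diameter_um[ok])
  }
  pts <- list(); skip <- list()
  for (v in unique(observations$vessel_id)) {
    o <- observations[observations$vessel_id == v, , drop = FALSE]
    o <- o[order(o$session_day), , drop = FALSE]
    for (i in seq_len(nrow(o))) {
      d <- o$session_day[i]
      j <- match(d + 1L, o$session_day)
      if (is.na(j)) next
      reason <- NULL
      if (is.na(o$diameter_um[i]) || o$diameter_um[i] <= 0)
        reason <- "no diameter at day t"
      else if (is.na(o$shear_rate_per_s[i]))
        reason <- "no velocity/shear at day t"
      else if (o$shear_rate_per_s[i] <= 0)
        reason <- "zero shear at day t (log10 undefined)"
      else if (is.na(o$diameter_um[j]))
        reason <- "no diameter at day t+1"
      if (is.null(reason)) {
        pts[[length(pts) + 1L]] <- data.frame(
          vessel_id = v, session_day = d,
          log10_shear = log10(o$shear_rate_per_s[i]),
          pct_change = percent_diameter_change(o$diameter_um[i],
                                               o$diameter_um[j]),
          stringsAsFactors = FALSE)
      } else {
        skip[[length(skip) + 1L]] <- data.frame(
          vessel_id = v, session_day = d, reason = reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(pts)) do.call(rbind, pts) else
    data.frame(vessel_id = character(), session_day = integer(),
               log10_shear = numeric(), pct_change = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skip)) do.call(rbind, skip) else
    data.frame(vessel_id = character(), session_day = integer(),
               reason = character(), stringsAsFactors = FALSE)
  class(out) <- c("remodeling_points", "data.frame")
  out
}

# one OLS fit of pct_change on log10_shear with bookkeeping
fit_ols_points <- function(points, excluded_ids, n_excluded) {
  n <- nrow(points)
  if (n < 3L) pf_stop("fewer than 3 usable remodeling points", "data")
  if (var(points$log10_shear) == 0)
    pf_stop("zero variance in log10 shear rate", "data")
  m <- lm(pct_change ~ log10_shear, data = points)
  sst <- sum((points$pct_change - mean(points$pct_change))^2)
  if (sst == 0) {
    r2 <- 0; p <- NA_real_
  } else {
    # summary.lm warns on numerically perfect fits; those are legitimate
    # here (noise-free synthetic cohorts), so the warning is muffled
    sm <- suppressWarnings(summary(m))
    r2 <- sm$r.squared
    p <- sm$coefficients["log10_shear", "Pr(>|t|)"]
  }
  structure(list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                 r_squared = r2, p_value = p, n_used = n,
                 n_excluded = n_excluded, excluded_ids = excluded_ids,
                 model = m),
            class = "remodeling_fit")
}

#' Regression of percent diameter change on log10 shear rate
#'
#' Ordinary least squares of next-day percent diameter change on the log10
#' of the same-day wall shear rate, reported both with and without the
#' study's outlier rule: points whose percent change exceeds
#' `exclude_above` (default 100%) are dropped from the with-exclusion fit
#' only. The rule is one-sided by design; no lower-tail exclusion is
#' applied. The p-value is the conventional two-sided t-test of zero slope.
#'
#' @param points A [pair_sessions()] result, or any data frame with
#'   `log10_shear` and `pct_change` (optionally `vessel_id`).
#' @param exclude_above Upper-tail exclusion threshold on `pct_change`, %.
#' @return A list of class `"remodeling_fit_pair"` with elements
#'   `with_exclusion` and `without_exclusion`, each a `"remodeling_fit"`:
#'   `slope` (%/log10(1/s)), `intercept` (%), `r_squared`, `p_value`,
#'   `n_used`, `n_excluded`, `excluded_ids`, and the underlying `model`
#'   (an [lm] object, e.g. for confidence intervals).
#' @examples
#' coh <- generate_cohort(cohort_truth(n_vessels = 20, noise_sd = 0))
#' fit_remodeling(pair_sessions(coh$observations))
#' @export
fit_remodeling <- function(points, exclude_above = 100) {
  if (!all(c("log10_shear", "pct_change") %in% names(points)))
    pf_stop("points need columns log10_shear and pct_change", "data")
  pts <- as.data.frame(points)
  out_idx <- which(pts$pct_change > exclude_above)
  excluded_ids <- if ("vessel_id" %in% names(pts))
    pts$vessel_id[out_idx] else as.character(out_idx)
  kept <- if (length(out_idx)) pts[-out_idx, , drop = FALSE] else pts
  structure(list(
    with_exclusion = fit_ols_points(kept, excluded_ids, length(out_idx)),
    without_exclusion = fit_ols_points(pts, character(), 0L),
    exclude_above = exclude_above),
    class = "remodeling_fit_pair")
}

#' @export
print.remodeling_fit <- function(x, ...) {
  cat(sprintf(
    "pct change = %.3f * log10(shear) + %.3f   (R2 = %.3f, p = %.3g, n = %d%s)\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n_used,
    if (x$n_excluded > 0)
      sprintf(", %d excluded >threshold", x$n_excluded) else ""))
  invisible(x)
}

#' @export
print.remodeling_fit_pair <- function(x, ...) {
  cat(sprintf("remodeling fit (outliers: pct change > %g%%)\n",
              x$exclude_above))
  cat("  with exclusion:    "); print(x$with_exclusion)
  cat("  without exclusion: "); print(x$without_exclusion)
  invisible(x)
}

#' Velocity-diameter correlation within postnatal age bins
#'
#' Pearson correlation of centerline velocity against lumen diameter for
#' observations whose postnatal age falls in each inclusive bin. Default
#' bins P2-P6 and P8-P12 correspond to the early and late halves of the
#' neonatal imaging window, between which the velocity-diameter coupling
#' strengthens. A bin with fewer than 3 usable observations is reported
#' with `NA` correlation rather than an error.
#'
#' @param observations Data frame with `age_day`, `diameter_um`,
#'   `velocity_mm_s`.
#' @param bins List of `c(age_lo, age_hi)` inclusive postnatal-day bins.
#' @return Data frame with columns `age_lo, age_hi, n, pearson_r, p_value`.
#' @export
age_bin_velocity_diameter <- function(observations,
                                      bins = list(c(2, 6), c(8, 12))) {
  req <- c("age_day", "diameter_um", "velocity_mm_s")
  miss <- setdiff(req, names(observations))
  if (length(miss))
    pf_stop(paste("observations lack column(s):",
                  paste(miss, collapse = ", ")), "data")
  ok <- !is.na(observations$diameter_um) & !is.na(observations$velocity_mm_s)
  o <- observations[ok, , drop = FALSE]
  do.call(rbind, lapply(bins, function(b) {
    sel <- o$age_day >= b[1] & o$age_day <= b[2]
    n <- sum(sel)
    if (n < 3L)
      return(data.frame(age_lo = b[1], age_hi = b[2], n = n,
                        pearson_r = NA_real_, p_value = NA_real_))
    ct <- cor.test(o$velocity_mm_s[sel], o$diameter_um[sel],
                   method = "pearson")
    data.frame(age_lo = b[1], age_hi = b[2], n = n,
               pearson_r = unname(ct$estimate), p_value = ct$p.value)
  }))
}
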