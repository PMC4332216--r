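#' Wall shear rate under Poiseuille flow
#'
#' For laminar (parabolic) flow in a cylindrical vessel, the wall shear
#' rate equals `4 * v_centerline / D`. With the centerline velocity in mm/s
#' and the diameter in um this is `4 * |v| * 1000 / D` per second. Only the
#' magnitude is meaningful: shear rate is nonnegative regardless of flow
#' direction. Shear stress is deliberately not computed, as it would
#' require the (unknown, hematocrit-dependent) blood viscosity.
#'
#' @param velocity Centerline red-blood-cell velocity, mm/s (signed;
#'   magnitude used). Vectorized.
#' @param diameter Lumen diameter, um (> 0). Vectorized.
#' @return Shear rate in 1/s.
#' @examples
#' shear_rate(1, 20)  # 200 /s
#' @export
shear_rate <- function(velocity, diameter) {
  if (any(diameter <= 0, na.rm = TRUE))
    pf_stop("diameter must be positive", "data")
  4 * abs(velocity) * 1000 / diameter
}

#' Assemble one vessel-session observation record
#'
#' Combines a diameter and a velocity measurement for one vessel on one
#' imaging day into the row format used by the longitudinal analysis,
#' computing the shear rate and propagating the below-40s quality flag from
#' the velocity estimate. A missing velocity yields a record with `NA`
#' velocity and shear rate, still usable for diameter-only tracking (it can
#' serve as the day t+1 endpoint of a session pair).
#'
#' @param vessel_id Vessel label.
#' @param age_day Postnatal age on this session, days.
#' @param session_day Session index (consecutive days differ by 1).
#' @param diameter A [fwhm_diameter()] estimate or a numeric diameter, um.
#' @param velocity A [estimate_velocity()] estimate, a numeric velocity in
#'   mm/s, or `NULL`/`NA` when no linescan is available.
#' @return One-row data frame with columns `vessel_id, age_day,
#'   session_day, diameter_um, velocity_mm_s, shear_rate_per_s, qc_flag`.
#' @export
build_observation <- function(vessel_id, age_day, session_day,
                              diameter, velocity = NULL) {
  check_id <- function(est) {
    vid <- attr(est, "vessel_id")
    if (!is.null(vid) && !identical(vid, vessel_id))
      pf_stop(sprintf("estimate labelled '%s' does not match vessel '%s'",
                      vid, vessel_id), "data")
  }
  qc <- FALSE
  if (inherits(diameter, "diameter_estimate")) {
    check_id(diameter)
    diameter <- diameter$diameter
  }
  if (inherits(velocity, "velocity_estimate")) {
    check_id(velocity)
    qc <- isTRUE(velocity$below_standard)
    velocity <- velocity$velocity
  }
  if (is.null(velocity)) velocity <- NA_real_
  sr <- if (is.na(velocity)) NA_real_ else shear_rate(velocity, diameter)
  data.frame(vessel_id = vessel_id, age_day = age_day,
             session_day = session_day, diameter_um = diameter,
             velocity_mm_s = velocity, shear_rate_per_s = sr,
             qc_flag = qc, stringsAsFactors = FALSE)
}
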