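# Trip-level foraging-effort metrics and per-segment kinematics.

#' Foraging-effort metrics for one trip
#'
#' Computes the four effort parameters — total duration (h), total distance
#' (cumulative great-circle km over consecutive fixes), maximal distance from
#' the colony (straight-line km to the most distal fix) and bearing (colony to
#' most distal fix; 0 = north, positive eastward) — plus the folded bearing
#' (absolute value, 0-180, used for repeatability), mean speed (km/h) and the
#' within-season timing covariate (days between departure and the peak
#' hatching date, possibly negative).
#'
#' @param t A resampled trip.
#' @param peak_hatch Date (or POSIXct, UTC) of the season's peak hatching.
#' @param p [qc_params()] (for the colony location).
#' @return One-row data.frame with the trip keys and all metrics.
#' @export
compute_metrics <- function(t, peak_hatch = NULL, p = qc_params()) {
  fx <- t$fixes
  stopifnot(nrow(fx) >= 2)
  dur_h <- as.numeric(difftime(t$return_time, t$departure, units = "hours"))
  stopifnot(dur_h > 0)
  n <- nrow(fx)
  step_km <- great_circle_km(fx$lon[-n], fx$lat[-n], fx$lon[-1], fx$lat[-1])
  d_col <- great_circle_km(fx$lon, fx$lat, p$colony[1], p$colony[2])
  i_max <- which.max(d_col)  # which.max: earliest fix wins on ties
  if (sum(abs(d_col - d_col[i_max]) < 1e-12) > 1)
    message("trip ", t$bird_id, "#", t$trip_index,
            ": tie for most distal fix; earliest kept")
  b <- bearing_deg(p$colony[1], p$colony[2], fx$lon[i_max], fx$lat[i_max])
  dsph <- if (is.null(peak_hatch)) NA_real_ else
    as.numeric(difftime(as.POSIXct(t$departure, tz = "UTC"),
                        as.POSIXct(peak_hatch, tz = "UTC"), units = "days"))
  data.frame(bird_id = t$bird_id, season = t$season, trip_index = t$trip_index,
             departure = t$departure, return_time = t$return_time,
             total_duration = dur_h,
             total_distance = sum(step_km),
             max_distance = d_col[i_max],
             bearing = b,
             bearing_folded = abs(b),
             mean_speed = sum(step_km) / dur_h,
             days_since_peak_hatch = dsph,
             completed_virtually = isTRUE(t$completed_virtually),
             recorded_fraction = t$recorded_fraction)
}

#' Metrics table for a set of trips
#'
#' @param trips List of resampled trips.
#' @param peak_hatch Named vector/list of peak hatching dates by season, a
#'   single date applied to all, or `NULL`.
#' @inheritParams compute_metrics
#' @return data.frame, one row per trip.
#' @export
trip_metrics_table <- function(trips, peak_hatch = NULL, p = qc_params()) {
  do.call(rbind, lapply(trips, function(t) {
    ph <- peak_hatch
    if (!is.null(ph) && !is.null(names(ph))) ph <- ph[[t$season]]
    compute_metrics(t, ph, p)
  }))
}

#' Span of bearings as a percentage of the full circle
#'
#' `(max - min) / 360 * 100`, rounded to the nearest integer for reporting.
#' Used to justify treating bearing as a linear rather than circular variable
#' when the observed span is well below the full circle.
#'
#' @param bearings Numeric vector of at least two bearings, degrees.
#' @return Integer percentage.
#' @export
bearing_span_pct <- function(bearings) {
  stopifnot(length(bearings) >= 2)
  round((max(bearings) - min(bearings)) / 360 * 100)
}

#' Kinematics of a fix segment
#'
#' Cumulative distance (km), mean speed (km/h, distance over elapsed time) and
#' sinuosity (cumulative distance over the straight-line first-to-last
#' distance; 1 = straight). Sinuosity is `NA` (flagged) when the straight-line
#' distance is zero (closed loop).
#'
#' @param fixes data.frame with `timestamp`, `lon`, `lat` (>= 2 rows).
#' @return One-row data.frame: `distance`, `mean_speed`, `sinuosity`,
#'   `sinuosity_defined`.
#' @export
segment_kinematics <- function(fixes) {
  n <- nrow(fixes)
  stopifnot(n >= 2)
  el_h <- as.numeric(difftime(fixes$timestamp[n], fixes$timestamp[1], units = "hours"))
  if (el_h <= 0) stop("segment has zero elapsed time")
  cum_km <- sum(great_circle_km(fixes$lon[-n], fixes$lat[-n],
                                fixes$lon[-1], fixes$lat[-1]))
  straight <- great_circle_km(fixes$lon[1], fixes$lat[1], fixes$lon[n], fixes$lat[n])
  defined <- straight > 0
  data.frame(distance = cum_km,
             mean_speed = cum_km / el_h,
             sinuosity = if (defined) cum_km / straight else NA_real_,
             sinuosity_defined = defined)
}
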