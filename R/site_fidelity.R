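# Foraging-site fidelity between consecutive trips: the mean
# nearest-neighbour distance (NND) between the central phases of trip n and
# trip n+1 of the same bird. Low NND = high fidelity.

#' Mean nearest-neighbour distance between two fix segments
#'
#' For each fix of the focal segment (trip n+1's central phase), the
#' great-circle distance to the nearest fix of the previous segment (trip n's
#' central phase); the NND is the mean of these over focal fixes. Asymmetric
#' by construction.
#'
#' @param focal data.frame of focal-segment fixes (`lon`, `lat`).
#' @param previous data.frame of previous-segment fixes.
#' @return Mean distance, km.
#' @export
nnd <- function(focal, previous) {
  stopifnot(nrow(focal) >= 1, nrow(previous) >= 1)
  mins <- vapply(seq_len(nrow(focal)), function(i) {
    min(great_circle_km(focal$lon[i], focal$lat[i], previous$lon, previous$lat))
  }, 0)
  mean(mins)
}

#' Fidelity table: NND between consecutive within-bird trip pairs
#'
#' Forms one record per pair of consecutive retained trips of the same bird
#' and season (trip indices differing by exactly one unless
#' `chain_retained = TRUE`, which pairs successive retained trips across
#' discarded intermediates), computes the NND between their central phases,
#' and optionally attaches the trip-pair ice covariates. Pairs whose central
#' phase has fewer than two focal fixes are skipped; birds with a single
#' retained trip contribute nothing.
#'
#' @param trips List of resampled trips.
#' @param m A [phase_model()].
#' @param peak_hatch Named list/vector of peak-hatch dates by season, one
#'   date, or `NULL` (timing covariate then NA).
#' @param fields Optional list of `ice_field`s named by date.
#' @param regions Optional named list of `study_region`s by season (or one
#'   region used for all). Required if `fields` given.
#' @param chain_retained Pair successive retained trips even when the
#'   intervening trip index was discarded (default FALSE: strict
#'   consecutive-index rule).
#' @param ice_mode Passed to [trip_pair_ice()].
#' @return data.frame, one row per pair: keys, `nnd` (km),
#'   `n_focal_points`, `days_since_peak_hatch` (focal trip), and when ice is
#'   supplied `mean_sic_pair`, `sic_difference`.
#' @export
fidelity_table <- function(trips, m = phase_model(), peak_hatch = NULL,
                           fields = NULL, regions = NULL,
                           chain_retained = FALSE,
                           ice_mode = c("union", "mean_of_means")) {
  ice_mode <- match.arg(ice_mode)
  key <- vapply(trips, function(t) paste(t$bird_id, t$season, sep = "\r"), "")
  recs <- list()
  for (k in unique(key)) {
    ts <- trips[key == k]
    ts <- ts[order(vapply(ts, `[[`, 0L, "trip_index"))]
    if (length(ts) < 2) {
      message("bird ", ts[[1]]$bird_id, "/", ts[[1]]$season,
              ": single retained trip, no fidelity record")
      next
    }
    for (i in seq_len(length(ts) - 1)) {
      t1 <- ts[[i]]; t2 <- ts[[i + 1]]
      if (!chain_retained && t2$trip_index != t1$trip_index + 1L) next
      prev <- extract_central_phase(t1, m)
      foc <- extract_central_phase(t2, m)
      if (attr(foc, "too_short") || nrow(prev) < 1) next
      ph <- peak_hatch
      if (!is.null(ph) && !is.null(names(ph))) ph <- ph[[t2$season]]
      rec <- data.frame(
        bird_id = t1$bird_id, season = t1$season,
        trip_n = t1$trip_index, trip_n1 = t2$trip_index,
        nnd = nnd(foc, prev),
        n_focal_points = nrow(foc),
        days_since_peak_hatch = if (is.null(ph)) NA_real_ else
          as.numeric(difftime(as.POSIXct(t2$departure, tz = "UTC"),
                              as.POSIXct(ph, tz = "UTC"), units = "days")))
      if (!is.null(fields)) {
        region <- if (inherits(regions, "study_region")) regions
                  else regions[[t1$season]]
        if (is.null(region)) stop("no region supplied for season ", t1$season)
        rec <- cbind(rec, .pair_ice(t1, t2, fields, region, ice_mode))
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  if (length(recs) == 0) return(NULL)
  do.call(rbind, recs)
}
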