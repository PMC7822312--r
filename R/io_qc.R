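# Reading raw GPS deployments, track QC, trip splitting, completion of
# truncated trips from nest-check returns, and regular resampling.

#' Quality-control parameters for track processing
#'
#' @param speed_threshold Maximum plausible travel speed, km/h. Fixes implying
#'   a faster great-circle speed from the last retained fix are dropped.
#' @param resample_step Regular resampling time step, minutes.
#' @param min_recorded_fraction Minimum fraction of the trip duration that must
#'   be covered by fixes for a truncated trip to be completed virtually rather
#'   than discarded (strictly greater-than rule).
#' @param colony_radius Radius around the colony within which a fix counts as
#'   "at the colony", km.
#' @param colony Colony location, `c(lon, lat)` in decimal degrees.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(speed_threshold = 10,
                      resample_step = 20,
                      min_recorded_fraction = 0.70,
                      colony_radius = 0.2,
                      colony = c(140.01, -66.66)) {
  stopifnot(speed_threshold > 0, resample_step > 0, colony_radius > 0,
            min_recorded_fraction > 0, min_recorded_fraction < 1,
            length(colony) == 2)
  structure(list(speed_threshold = speed_threshold,
                 resample_step = resample_step,
                 min_recorded_fraction = min_recorded_fraction,
                 colony_radius = colony_radius,
                 colony = colony),
            class = "qc_params")
}

.new_deployment <- function(bird_id, season, fixes, nest_checks = NULL) {
  structure(list(bird_id = bird_id, season = season,
                 fixes = fixes, nest_checks = nest_checks),
            class = "cpf_deployment")
}

.new_trip <- function(bird_id, season, trip_index, fixes,
                      departure, return_time,
                      ends_at_colony = TRUE,
                      completed_virtually = FALSE,
                      recorded_fraction = NA_real_,
                      resampled = FALSE) {
  structure(list(bird_id = bird_id, season = season, trip_index = trip_index,
                 fixes = fixes, departure = departure, return_time = return_time,
                 ends_at_colony = ends_at_colony,
                 completed_virtually = completed_virtually,
                 recorded_fraction = recorded_fraction,
                 resampled = resampled),
            class = "cpf_trip")
}

#' @export
print.cpf_trip <- function(x, ...) {
  cat(sprintf("<trip %s/%s #%d: %d fixes, %.1f h%s%s>\n",
              x$bird_id, x$season, x$trip_index, nrow(x$fixes),
              as.numeric(difftime(x$return_time, x$departure, units = "hours")),
              if (isTRUE(x$completed_virtually)) ", virtually completed" else "",
              if (isTRUE(x$resampled)) ", resampled" else ""))
  invisible(x)
}

.parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

#' Read raw GPS track files into deployments
#'
#' Each input CSV must have columns `bird_id`, `season`, `timestamp`
#' (ISO-8601, UTC), `lon`, `lat`. Rows with unparseable timestamps or
#' out-of-range coordinates are dropped with a warning. One deployment is
#' returned per (bird_id, season) pair, rows kept in file order.
#'
#' @param paths Character vector of CSV file paths.
#' @return List of deployments.
#' @export
read_tracks <- function(paths) {
  rows <- do.call(rbind, lapply(paths, function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("bird_id", "season", "timestamp", "lon", "lat")
    if (!all(need %in% names(d))) {
      stop("track file ", p, " must have columns: ", paste(need, collapse = ", "))
    }
    d[need]
  }))
  if (nrow(rows) == 0) stop("no track rows found")
  ts <- .parse_utc(rows$timestamp)
  bad <- is.na(ts) | !is.finite(rows$lon) | !is.finite(rows$lat) |
    abs(rows$lat) > 90 | abs(rows$lon) > 180
  if (any(bad)) {
    warning(sum(bad), " malformed track row(s) dropped")
    rows <- rows[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  if (nrow(rows) == 0) stop("no valid track rows after parsing")
  key <- paste(rows$bird_id, rows$season, sep = "\r")
  lapply(split(seq_len(nrow(rows)), factor(key, levels = unique(key))),
         function(i) {
           .new_deployment(rows$bird_id[i[1]], rows$season[i[1]],
                           data.frame(timestamp = ts[i],
                                      lon = rows$lon[i], lat = rows$lat[i]))
         }) |> unname()
}

#' Read nest-check return times
#'
#' @param path CSV with columns `bird_id`, `season`, `trip_index`,
#'   `observed_return` (ISO-8601 UTC).
#' @return data.frame with parsed `observed_return`.
#' @export
read_nest_checks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "season", "trip_index", "observed_return")
  stopifnot(all(need %in% names(d)))
  d$observed_return <- .parse_utc(d$observed_return)
  d
}

#' Clean a deployment's fixes
#'
#' Removes fixes with missing timestamps or in the Northern Hemisphere,
#' exact duplicates (same timestamp, lon and lat), same-timestamp conflicts
#' (first kept), then applies a forward-pass speed filter: iterating in time
#' order, any fix whose implied great-circle speed from the last retained fix
#' exceeds `p$speed_threshold` km/h is dropped.
#'
#' @param dep A deployment from [read_tracks()].
#' @param p [qc_params()].
#' @return The deployment with cleaned, strictly time-increasing fixes.
#' @export
clean_fixes <- function(dep, p = qc_params()) {
  fx <- dep$fixes
  stopifnot(nrow(fx) > 0)
  fx <- fx[!is.na(fx$timestamp) & fx$lat <= 0, , drop = FALSE]
  fx <- fx[order(fx$timestamp), , drop = FALSE]
  dup <- duplicated(fx[c("timestamp", "lon", "lat")])
  fx <- fx[!dup, , drop = FALSE]
  same_t <- duplicated(fx$timestamp)
  if (any(same_t)) {
    message(sum(same_t), " same-timestamp fix(es) with differing positions: first kept")
    fx <- fx[!same_t, , drop = FALSE]
  }
  if (nrow(fx) == 0) stop("deployment fully filtered")
  keep <- logical(nrow(fx))
  keep[1] <- TRUE
  last <- 1L
  for (i in seq_len(nrow(fx))[-1]) {
    dt_h <- as.numeric(difftime(fx$timestamp[i], fx$timestamp[last], units = "hours"))
    d_km <- great_circle_km(fx$lon[last], fx$lat[last], fx$lon[i], fx$lat[i])
    if (d_km / dt_h <= p$speed_threshold) {
      keep[i] <- TRUE
      last <- i
    }
  }
  fx <- fx[keep, , drop = FALSE]
  if (nrow(fx) == 0) stop("deployment fully filtered")
  rownames(fx) <- NULL
  dep$fixes <- fx
  dep
}

#' Split a cleaned deployment into trips
#'
#' Fixes are partitioned into maximal runs outside the colony radius; each
#' run, bracketed by its last-inside and first-inside colony fixes (when
#' present), becomes one trip. Colony dwell fixes between excursions belong
#' to no trip interior. Trips are numbered chronologically from 1.
#'
#' @inheritParams clean_fixes
#' @return List of trips (possibly empty).
#' @export
split_trips <- function(dep, p = qc_params()) {
  fx <- dep$fixes
  d_col <- great_circle_km(fx$lon, fx$lat, p$colony[1], p$colony[2])
  outside <- d_col > p$colony_radius
  if (!any(outside)) {
    message("deployment ", dep$bird_id, "/", dep$season,
            ": no fix leaves the colony radius; zero trips")
    return(list())
  }
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- list()
  k <- 0L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    from <- if (i0 > 1L) i0 - 1L else i0
    ends_at_colony <- i1 < nrow(fx)
    to <- if (ends_at_colony) i1 + 1L else i1
    seg <- fx[from:to, , drop = FALSE]
    rownames(seg) <- NULL
    k <- k + 1L
    trips[[k]] <- .new_trip(dep$bird_id, dep$season, k, seg,
                            departure = seg$timestamp[1],
                            return_time = seg$timestamp[nrow(seg)],
                            ends_at_colony = ends_at_colony,
                            recorded_fraction = if (ends_at_colony) 1 else NA_real_)
  }
  trips
}

#' Complete a truncated trip from a nest-check return, or discard it
#'
#' A trip that already ends at the colony is returned unchanged (recorded
#' fraction 1). For a truncated trip, the total trip duration is taken as
#' `observed_return - departure`; when the fraction of that duration covered
#' by fixes exceeds `p$min_recorded_fraction`, a virtual colony fix at the
#' observed return time is appended and the trip flagged as virtually
#' completed; otherwise `NULL` is returned (trip discarded).
#'
#' @param t A trip from [split_trips()].
#' @param observed_return POSIXct (UTC) return time from nest monitoring.
#' @param p [qc_params()].
#' @return The (possibly completed) trip, or `NULL` if discarded.
#' @export
complete_or_discard <- function(t, observed_return = NULL, p = qc_params()) {
  if (t$ends_at_colony) {
    t$recorded_fraction <- 1
    t$completed_virtually <- FALSE
    return(t)
  }
  if (is.null(observed_return) || is.na(observed_return)) {
    message("trip ", t$bird_id, "#", t$trip_index,
            ": truncated with no nest-check return; discarded")
    return(NULL)
  }
  if (observed_return < t$departure) stop("observed return earlier than departure")
  total_h <- as.numeric(difftime(observed_return, t$departure, units = "hours"))
  rec_h <- as.numeric(difftime(t$fixes$timestamp[nrow(t$fixes)], t$departure,
                               units = "hours"))
  frac <- min(rec_h / total_h, 1)
  if (frac <= p$min_recorded_fraction + 1e-9) {  # strict > rule, fp-safe
    message("trip ", t$bird_id, "#", t$trip_index, ": only ",
            round(100 * frac), "% of duration recorded; discarded")
    return(NULL)
  }
  t$fixes <- rbind(t$fixes,
                   data.frame(timestamp = observed_return,
                              lon = p$colony[1], lat = p$colony[2]))
  rownames(t$fixes) <- NULL
  t$return_time <- observed_return
  t$completed_virtually <- TRUE
  t$recorded_fraction <- frac
  t
}

#' Resample a trip to a regular time step
#'
#' Produces fixes at `departure + k * resample_step` minutes, with lon and lat
#' linearly interpolated in time between the bracketing original fixes. The
#' first resampled fix is the departure fix exactly; no fix is placed after
#' the return time.
#'
#' @inheritParams complete_or_discard
#' @return The trip with regular fixes and `resampled = TRUE`; trips shorter
#'   than one step are left as their endpoint fixes with `resampled = FALSE`.
#' @export
resample_trip <- function(t, p = qc_params()) {
  fx <- t$fixes
  stopifnot(nrow(fx) >= 2)
  step_s <- p$resample_step * 60
  dur_s <- as.numeric(difftime(t$return_time, t$departure, units = "secs"))
  if (dur_s < step_s) {
    message("trip ", t$bird_id, "#", t$trip_index,
            ": shorter than one resampling step; left at endpoint fixes")
    t$fixes <- fx[c(1, nrow(fx)), , drop = FALSE]
    rownames(t$fixes) <- NULL
    t$resampled <- FALSE
    return(t)
  }
  tt <- as.numeric(fx$timestamp)
  grid <- as.numeric(t$departure) + step_s * (0:floor(dur_s / step_s))
  t$fixes <- data.frame(
    timestamp = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
    lon = stats::approx(tt, fx$lon, xout = grid, rule = 2)$y,
    lat = stats::approx(tt, fx$lat, xout = grid, rule = 2)$y)
  t$resampled <- TRUE
  t
}

#' QC a set of deployments end to end
#'
#' Cleans fixes, splits trips, completes or discards truncated trips using
#' the nest-check table, and resamples retained trips. Trip indices are the
#' chronological indices from splitting, so nest checks keyed by
#' (bird_id, season, trip_index) match.
#'
#' @param deployments List of deployments from [read_tracks()].
#' @param nest_checks data.frame from [read_nest_checks()], or `NULL`.
#' @param p [qc_params()].
#' @return List of retained, resampled trips.
#' @export
qc_deployments <- function(deployments, nest_checks = NULL, p = qc_params()) {
  if (!is.null(nest_checks) && is.character(nest_checks$observed_return))
    nest_checks$observed_return <- .parse_utc(nest_checks$observed_return)
  out <- list()
  for (dep in deployments) {
    dep <- clean_fixes(dep, p)
    for (t in split_trips(dep, p)) {
      obs <- NULL
      if (!is.null(nest_checks)) {
        m <- nest_checks$bird_id == t$bird_id &
          nest_checks$season == t$season &
          nest_checks$trip_index == t$trip_index
        if (any(m)) obs <- nest_checks$observed_return[which(m)[1]]
      }
      t <- complete_or_discard(t, obs, p)
      if (!is.null(t)) out[[length(out) + 1L]] <- resample_trip(t, p)
    }
  }
  out
}

#' Cohort bookkeeping: individuals and trips per season
#'
#' Summarizes a retained-trip set the way cohort tables are reported:
#' per season, the number of individuals tracked for each trip count, the
#' total individuals, total trips, and mean +/- SD trips per bird.
#'
#' @param trips List of trips.
#' @return List of class `cohort_summary` with components `counts` (season,
#'   n_trips_per_bird, n_ind), `per_season` and `overall`.
#' @export
summarize_cohort <- function(trips) {
  stopifnot(length(trips) > 0)
  d <- data.frame(bird_id = vapply(trips, `[[`, "", "bird_id"),
                  season = vapply(trips, `[[`, "", "season"))
  per_bird <- stats::aggregate(rep(1L, nrow(d)),
                               by = d[c("season", "bird_id")], FUN = sum)
  names(per_bird)[3] <- "n_trips"
  counts <- stats::aggregate(rep(1L, nrow(per_bird)),
                             by = list(season = per_bird$season,
                                       n_trips_per_bird = per_bird$n_trips),
                             FUN = sum)
  names(counts)[3] <- "n_ind"
  counts <- counts[order(counts$season, counts$n_trips_per_bird), ]
  rownames(counts) <- NULL
  per_season <- do.call(rbind, lapply(split(per_bird, per_bird$season), function(s) {
    data.frame(season = s$season[1], n_ind = nrow(s), n_trip = sum(s$n_trips),
               mean_trips = mean(s$n_trips), sd_trips = stats::sd(s$n_trips))
  }))
  rownames(per_season) <- NULL
  overall <- data.frame(n_ind = nrow(per_bird), n_trip = sum(per_bird$n_trips),
                        mean_trips = mean(per_bird$n_trips),
                        sd_trips = stats::sd(per_bird$n_trips))
  structure(list(counts = counts, per_season = per_season, overall = overall),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$per_season, row.names = FALSE)
  cat(sprintf("Total: %d individuals, %d trips (%.2f +/- %.2f trips/bird)\n",
              x$overall$n_ind, x$overall$n_trip,
              x$overall$mean_trips, x$overall$sd_trips))
  invisible(x)
}

#' Totals from a printed individuals-by-trip-count distribution
#'
#' Given the marginal distribution of individuals over trip counts (as
#' published cohort tables print it), computes the implied totals: number of
#' individuals, number of trips, and mean and SD of trips per bird.
#'
#' @param n_trips Vector of trip counts.
#' @param n_ind Number of individuals with each trip count.
#' @return data.frame with `n_individuals`, `n_trips_total`, `mean_trips`,
#'   `sd_trips`.
#' @export
trip_count_totals <- function(n_trips, n_ind) {
  stopifnot(length(n_trips) == length(n_ind), all(n_ind >= 0))
  expanded <- rep(n_trips, n_ind)
  data.frame(n_individuals = as.integer(sum(n_ind)),
             n_trips_total = as.integer(sum(n_trips * n_ind)),
             mean_trips = mean(expanded),
             sd_trips = stats::sd(expanded))
}
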