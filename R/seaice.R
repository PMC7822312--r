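# Daily gridded sea-ice concentration (SIC): container, plain-text I/O,
# regridding, along-track extraction and regional / trip-window averaging.
#
# A field is a regular lon/lat grid of daily concentration percentages with
# an NA mask. Cell ownership is half-open: a point belongs to the cell whose
# west and south edges it is on.

#' Construct a daily sea-ice concentration field
#'
#' @param date Date of the field.
#' @param cell_km Nominal cell size, km (e.g. 6.25 or 12.5).
#' @param lon,lat Ascending, regularly spaced cell-center coordinates.
#' @param grid Matrix of concentration percent, `length(lat)` rows x
#'   `length(lon)` columns. Values outside `[0, 100]` are masked (NA) with a
#'   warning.
#' @return List of class `ice_field`.
#' @export
ice_field <- function(date, cell_km, lon, lat, grid) {
  stopifnot(is.matrix(grid), nrow(grid) == length(lat), ncol(grid) == length(lon),
            !is.unsorted(lon), !is.unsorted(lat))
  bad <- !is.na(grid) & (grid < 0 | grid > 100)
  if (any(bad)) {
    warning(sum(bad), " out-of-range concentration value(s) masked")
    grid[bad] <- NA
  }
  structure(list(date = as.Date(date), cell_km = cell_km,
                 lon = lon, lat = lat, grid = grid),
            class = "ice_field")
}

#' @export
print.ice_field <- function(x, ...) {
  cat(sprintf("<ice field %s: %d x %d cells (%.2f km), mean %.1f%%>\n",
              format(x$date), length(x$lat), length(x$lon), x$cell_km,
              mean(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' Write daily ice fields as plain-text CSV, one file per day
#'
#' Each file `sic_<date>.csv` has a metadata header line
#' (`# date=...,cell_km=...`) followed by `lon,lat,sic` rows at full double
#' precision, so a round trip reproduces the grid exactly.
#'
#' @param fields List of `ice_field`s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_icefields <- function(fields, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(fields, function(f) {
    path <- file.path(dir, paste0("sic_", format(f$date), ".csv"))
    cc <- expand.grid(lon = f$lon, lat = f$lat)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# date=%s,cell_km=%.17g", format(f$date), f$cell_km), con)
    writeLines("lon,lat,sic", con)
    writeLines(sprintf("%.17g,%.17g,%s", cc$lon, cc$lat,
                       ifelse(is.na(t(f$grid)), "NA",
                              sprintf("%.17g", t(f$grid)))), con)
    path
  }, "")
  invisible(paths)
}

#' Load daily ice fields from a directory of per-day CSVs
#'
#' @param dir Directory written by [write_icefields()].
#' @param dates Optional Date vector that must be fully covered; missing days
#'   raise an error listing them.
#' @return List of `ice_field`s in date order, named by date.
#' @export
load_icefields <- function(dir, dates = NULL) {
  paths <- sort(list.files(dir, pattern = "^sic_.*\\.csv$", full.names = TRUE))
  if (length(paths) == 0) stop("no ice field files in ", dir)
  fields <- lapply(paths, function(p) {
    hdr <- readLines(p, n = 1)
    meta <- sub("^# ", "", hdr)
    kv <- strsplit(strsplit(meta, ",")[[1]], "=")
    vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    d <- utils::read.csv(p, comment.char = "#")
    lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
    g <- matrix(NA_real_, length(lat), length(lon))
    g[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$sic
    ice_field(as.Date(vals[["date"]]), as.numeric(vals[["cell_km"]]), lon, lat, g)
  })
  names(fields) <- vapply(fields, function(f) format(f$date), "")
  fields <- fields[order(names(fields))]
  if (!is.null(dates)) {
    miss <- setdiff(format(as.Date(dates)), names(fields))
    if (length(miss) > 0)
      stop("missing ice fields for: ", paste(miss, collapse = ", "))
  }
  fields
}

#' Sample an ice field at points
#'
#' Value of the containing cell, no interpolation; cell ownership is
#' half-open with west and south edges inclusive. Points outside the grid
#' extent are masked (NA) with a warning.
#'
#' @param f An `ice_field`.
#' @param lon,lat Point coordinates (vectorised).
#' @return Numeric vector of concentrations (percent) or NA.
#' @export
sample_at <- function(f, lon, lat) {
  dlon <- if (length(f$lon) > 1) f$lon[2] - f$lon[1] else f$cell_km
  dlat <- if (length(f$lat) > 1) f$lat[2] - f$lat[1] else f$cell_km
  ci <- findInterval(lon, c(f$lon - dlon / 2, f$lon[length(f$lon)] + dlon / 2))
  ri <- findInterval(lat, c(f$lat - dlat / 2, f$lat[length(f$lat)] + dlat / 2))
  out <- rep(NA_real_, length(lon))
  ok <- ci >= 1 & ci <= length(f$lon) & ri >= 1 & ri <= length(f$lat)
  if (any(!ok)) warning(sum(!ok), " point(s) outside the ice grid extent; masked")
  out[ok] <- f$grid[cbind(ri[ok], ci[ok])]
  out
}

#' Regrid a coarse field onto a grid of half the cell size
#'
#' Nearest-neighbour (containing-cell) assignment: every fine cell takes the
#' value of the coarse cell it falls in, so each coarse cell maps to a 2 x 2
#' block of equal value and values are unchanged.
#'
#' @param coarse An `ice_field` (e.g. 12.5 km).
#' @return An `ice_field` at half the cell size over the same extent.
#' @export
regrid_to_fine <- function(coarse) {
  half_lon <- (coarse$lon[2] - coarse$lon[1]) / 4
  half_lat <- (coarse$lat[2] - coarse$lat[1]) / 4
  fine_lon <- sort(c(coarse$lon - half_lon, coarse$lon + half_lon))
  fine_lat <- sort(c(coarse$lat - half_lat, coarse$lat + half_lat))
  cc <- expand.grid(lon = fine_lon, lat = fine_lat)
  vals <- sample_at(coarse, cc$lon, cc$lat)
  ice_field(coarse$date, coarse$cell_km / 2, fine_lon, fine_lat,
            matrix(vals, length(fine_lat), length(fine_lon), byrow = TRUE))
}

#' Pearson correlation of per-fix extractions at two grid resolutions
#'
#' @param fields_a,fields_b Lists of `ice_field`s named by date (as from
#'   [load_icefields()]), covering every fix date.
#' @param fixes data.frame with `timestamp`, `lon`, `lat`.
#' @return List with `r` (Pearson correlation) and `n` (valid pairs).
#' @export
resolution_correlation <- function(fields_a, fields_b, fixes) {
  day <- format(as.Date(fixes$timestamp, tz = "UTC"))
  va <- vb <- rep(NA_real_, nrow(fixes))
  for (d in unique(day)) {
    i <- day == d
    if (is.null(fields_a[[d]]) || is.null(fields_b[[d]]))
      stop("missing ice field for ", d)
    va[i] <- sample_at(fields_a[[d]], fixes$lon[i], fixes$lat[i])
    vb[i] <- sample_at(fields_b[[d]], fixes$lon[i], fixes$lat[i])
  }
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3) stop("fewer than 3 valid extraction pairs")
  list(r = stats::cor(va[ok], vb[ok]), n = sum(ok))
}

#' Define a study region polygon
#'
#' @param kind `"whole_study_area"` or `"annual_prospected_area"`.
#' @param lon,lat Polygon vertex coordinates (simple ring, open or closed).
#' @param season Season label for annual regions.
#' @return List of class `study_region` with the polygon and its area (km^2).
#' @export
study_region <- function(kind = c("whole_study_area", "annual_prospected_area"),
                         lon, lat, season = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(length(lon) == length(lat), length(lon) >= 3)
  if (lon[1] == lon[length(lon)] && lat[1] == lat[length(lat)]) {
    lon <- lon[-length(lon)]; lat <- lat[-length(lat)]
  }
  structure(list(kind = kind, lon = lon, lat = lat, season = season,
                 area_km2 = polygon_area_km2(lon, lat)),
            class = "study_region")
}

#' The fixed whole-study-area rectangle
#'
#' 64-67 degrees S, 137-143 degrees E: the regional scale against which
#' annual trip-scale conditions are compared.
#' @return A `study_region`.
#' @export
whole_study_area <- function() {
  study_region("whole_study_area",
               lon = c(137, 143, 143, 137), lat = c(-67, -67, -64, -64))
}

#' Annually prospected area of a season's trips
#'
#' Convex hull of all retained fixes of the season, as a polygon region;
#' the area is computed in a local equal-area projection.
#'
#' @param trips List of trips from one season.
#' @return A `study_region` of kind `annual_prospected_area`.
#' @export
annual_prospected_area <- function(trips) {
  stopifnot(length(trips) >= 1)
  lon <- unlist(lapply(trips, function(t) t$fixes$lon))
  lat <- unlist(lapply(trips, function(t) t$fixes$lat))
  h <- grDevices::chull(lon, lat)
  if (length(h) < 3) stop("fewer than 3 non-collinear fixes; no hull")
  study_region("annual_prospected_area", lon = lon[h], lat = lat[h],
               season = trips[[1]]$season)
}

.region_cell_mean <- function(f, region) {
  cc <- expand.grid(lon = f$lon, lat = f$lat)
  inside <- .points_in_polygon(cc$lon, cc$lat, region$lon, region$lat)
  if (!any(inside)) stop("no grid cell centers inside the region polygon")
  vals <- t(f$grid)[inside]  # expand.grid varies lon fastest = t(grid) order
  mean(vals, na.rm = TRUE)
}

#' Mean sea-ice concentration in a region over a set of days
#'
#' For each day: mean over unmasked cells whose centers fall inside the
#' region polygon; then the mean over days. Trip windows expand to full
#' day sequences upstream, so `window` is always the explicit list of days
#' to average (duplicates collapse).
#'
#' @param fields List of `ice_field`s named by date.
#' @param region A `study_region`.
#' @param window Date vector; every date must be loaded.
#' @return Mean concentration, percent.
#' @export
mean_sic_region <- function(fields, region, window) {
  window <- unique(as.Date(window))
  days <- format(window)
  miss <- setdiff(days, names(fields))
  if (length(miss) > 0) stop("missing ice fields for: ", paste(miss, collapse = ", "))
  mean(vapply(days, function(d) .region_cell_mean(fields[[d]], region), 0))
}

#' Mean sea-ice concentration along a central-phase segment
#'
#' Arithmetic mean of the per-fix sampled daily concentrations; masked fixes
#' are excluded and counted.
#'
#' @param segment data.frame of fixes (`timestamp`, `lon`, `lat`).
#' @param fields List of `ice_field`s named by date.
#' @return List with `mean_sic` (percent), `n_used`, `n_masked`.
#' @export
mean_sic_central_phase <- function(segment, fields) {
  stopifnot(nrow(segment) > 0)
  day <- format(as.Date(segment$timestamp, tz = "UTC"))
  miss <- setdiff(unique(day), names(fields))
  if (length(miss) > 0) stop("missing ice fields for: ", paste(miss, collapse = ", "))
  vals <- rep(NA_real_, nrow(segment))
  for (d in unique(day)) {
    i <- day == d
    vals[i] <- sample_at(fields[[d]], segment$lon[i], segment$lat[i])
  }
  if (all(is.na(vals))) stop("all fixes masked in the ice fields")
  list(mean_sic = mean(vals, na.rm = TRUE),
       n_used = sum(!is.na(vals)), n_masked = sum(is.na(vals)))
}

.trip_days <- function(t) {
  seq(as.Date(t$departure, tz = "UTC"), as.Date(t$return_time, tz = "UTC"),
      by = "day")
}

#' Ice covariates for a pair of consecutive trips
#'
#' `mean_sic_pair` is the mean concentration in the region over the two
#' trips' combined date span (`mode = "union"`, default) or the mean of the
#' two per-trip means (`mode = "mean_of_means"`). `sic_difference` is the
#' trip-n mean minus the trip-(n+1) mean: positive when the ice receded
#' between the trips.
#'
#' @param trip_n,trip_n1 Consecutive trips of the same bird
#'   (`trip_index` differing by one).
#' @param fields List of `ice_field`s named by date.
#' @param region A `study_region` (normally the annually prospected area).
#' @param mode Averaging convention for `mean_sic_pair`.
#' @return data.frame with `mean_sic_pair` and `sic_difference` (percent).
#' @export
trip_pair_ice <- function(trip_n, trip_n1, fields, region,
                          mode = c("union", "mean_of_means")) {
  mode <- match.arg(mode)
  if (!identical(trip_n$bird_id, trip_n1$bird_id) ||
      trip_n1$trip_index != trip_n$trip_index + 1L)
    stop("trips must be consecutive trips of the same bird")
  .pair_ice(trip_n, trip_n1, fields, region, mode)
}

.pair_ice <- function(trip_n, trip_n1, fields, region, mode) {
  m1 <- mean_sic_region(fields, region, .trip_days(trip_n))
  m2 <- mean_sic_region(fields, region, .trip_days(trip_n1))
  pair <- if (mode == "union") {
    mean_sic_region(fields, region,
                    unique(c(.trip_days(trip_n), .trip_days(trip_n1))))
  } else {
    mean(c(m1, m2))
  }
  data.frame(mean_sic_pair = pair, sic_difference = m1 - m2)
}
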