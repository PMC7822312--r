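# Fixture builders and independent oracles used across the suite.

COLONY <- c(140.01, -66.66)
KM_PER_DEG_LAT <- 2 * pi * 6371.0088 / 360  # exact on the package's sphere

utc <- function(x) as.POSIXct(x, tz = "UTC")

# fixes at given minutes after an epoch, with lon/lat vectors
make_fixes <- function(min_after, lon, lat, t0 = utc("2016-01-05 00:00:00")) {
  data.frame(timestamp = t0 + min_after * 60, lon = lon, lat = lat)
}

make_deployment <- function(fixes, bird_id = "b1", season = "2015-16") {
  tripfidelity:::.new_deployment(bird_id, season, fixes)
}

make_trip <- function(fixes, bird_id = "b1", season = "2015-16",
                      trip_index = 1L, ends_at_colony = TRUE) {
  tripfidelity:::.new_trip(bird_id, season, trip_index, fixes,
                           departure = fixes$timestamp[1],
                           return_time = fixes$timestamp[nrow(fixes)],
                           ends_at_colony = ends_at_colony,
                           recorded_fraction = if (ends_at_colony) 1 else NA_real_,
                           resampled = TRUE)
}

# straight out-and-back excursion due north of the colony, regular cadence
make_outback_trip <- function(max_km = 20, n_leg = 30, step_min = 20, ...) {
  lat_peak <- COLONY[2] + max_km / KM_PER_DEG_LAT
  lat <- c(seq(COLONY[2], lat_peak, length.out = n_leg + 1),
           seq(lat_peak, COLONY[2], length.out = n_leg + 1)[-1])
  make_trip(make_fixes(seq_along(lat) * step_min - step_min,
                       rep(COLONY[1], length(lat)), lat), ...)
}

# independent distance oracle: spherical law of cosines, same radius
slc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371.0088 * acos(pmin(pmax(d, -1), 1))
}

# quadratic all-pairs NND oracle
nnd_brute <- function(focal, previous) {
  dm <- outer(seq_len(nrow(focal)), seq_len(nrow(previous)),
              function(i, j) great_circle_km(focal$lon[i], focal$lat[i],
                                             previous$lon[j], previous$lat[j]))
  mean(apply(dm, 1, min))
}

# ray-casting point-in-polygon oracle
pip_raycast <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

# brute-force three-segment fit via lm over an explicit grid (oracle)
fit_three_segment_oracle <- function(profile, grid_step) {
  x <- profile$pct_duration; y <- profile$pct_maxdist
  cand <- seq(grid_step, 100 - grid_step, by = grid_step)
  best <- c(NA, NA); best_rss <- Inf
  for (f1 in cand) for (f2 in cand[cand > f1]) {
    X <- cbind(1, x, pmax(x - f1, 0), pmax(x - f2, 0))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(f1, f2) }
  }
  list(f1 = best[1], f2 = best[2], rss = best_rss)
}

# noise-free / noisy trapezoid profile with corners at f1, f2
make_trapezoid_profile <- function(f1 = 30, f2 = 70, n = 2000, noise_sd = 0,
                                   seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, 100)
  y <- ifelse(x < f1, 100 * x / f1, ifelse(x <= f2, 100,
                                           100 * (100 - x) / (100 - f2)))
  data.frame(pct_duration = x, pct_maxdist = y + rnorm(n, 0, noise_sd))
}
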