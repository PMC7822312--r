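# Seeded synthetic study generator: a colony of central-place foragers
# performing multi-trip, three-phase foraging excursions over daily receding
# sea-ice fields, with nest checks, peak-hatch dates and a truth table for
# every upstream estimator.
#
# Trips are correlated random walks built in a local planar frame (km) around
# the colony and mapped to lon/lat; adequate below ~150 km from the colony.
# Each bird carries trait means (heading, log maximal distance) drawn from
# population distributions with known between- and within-individual SDs, so
# the true repeatability of each trait is known by construction.

.KM_PER_DEG_LAT <- 111.195  # 2*pi*R/360 on the 6371.0088 km sphere

.xy_to_lonlat <- function(x, y, colony) {
  list(lon = colony[1] + x / (.KM_PER_DEG_LAT * cos(colony[2] * pi / 180)),
       lat = colony[2] + y / .KM_PER_DEG_LAT)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a chick-rearing tracking study: ~130 birds recorded over
#' 2-9 trips (trip-count distribution as published cohort tables), maximal
#' distances tens of km with moderate individual repeatability, three-phase
#' trips with true breakpoints at 30% and 70% of trip duration, and daily
#' 6.25-km ice fields receding through the season.
#'
#' @param n_birds Number of birds.
#' @param trips_per_bird Single count, vector (recycled), or `NULL` to sample
#'   from the 2-9 trip-count distribution of the reference cohort.
#' @param seasons Character vector of season labels; birds are split evenly
#'   across seasons (each bird tracked in one season).
#' @param season_shift Named per-season additive shift on log maximal
#'   distance (year effect); default none.
#' @param phase_fractions_true True breakpoints `c(f1, f2)`, percent of trip
#'   duration.
#' @param heading_mean Population mean heading to the foraging patch, degrees.
#' @param heading_between_sd,heading_within_sd Between-/within-individual SD
#'   of trip heading, degrees.
#' @param logdist_mean Population mean of log maximal distance (log km).
#' @param logdist_between_sd,logdist_within_sd Between-/within-individual SD
#'   of log maximal distance.
#' @param fidelity_mode `"faithful"`: per-trip patches centred on the bird's
#'   own patch (trait variance components as configured); `"explorer"`: every
#'   trip draws a fresh patch from the population distribution (no individual
#'   component; true repeatability 0).
#' @param transit_speed,forage_speed Speeds, km/h.
#' @param transit_turn_sd Angular noise of transit headings, degrees/step.
#' @param forage_pull_km Patch radius beyond which the foraging walk is
#'   pulled back toward the patch centre, km.
#' @param step_min Raw GPS sampling interval, minutes.
#' @param truncation_prob Probability a trip's recording stops early.
#' @param truncation_fraction Fraction of the trip duration recorded when
#'   truncated.
#' @param nest_check_interval_h Nest-monitoring interval; observed returns
#'   lag true returns by up to this many hours.
#' @param dup_prob,spike_prob Per-trip probabilities of an injected duplicate
#'   row and of a teleport outlier (exercise the QC filters).
#' @param ice_south_sic,ice_north_sic Day-0 concentrations at the south and
#'   north edge of the study area (latitudinal gradient), percent.
#' @param ice_recession_per_day Daily multiplicative recession rate (0.02 =
#'   2%/day).
#' @param ice_noise_sd SD of the smooth daily noise added to the fields.
#' @param ice_cell_km Ice grid cell size, km.
#' @param max_range_km Patches beyond this range raise an error (planar
#'   approximation limit).
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_birds = 129,
                       trips_per_bird = NULL,
                       seasons = "2015-16",
                       season_shift = NULL,
                       phase_fractions_true = c(30, 70),
                       heading_mean = 8,
                       heading_between_sd = 22,
                       heading_within_sd = 28,
                       logdist_mean = log(30),
                       logdist_between_sd = 0.30,
                       logdist_within_sd = 0.35,
                       fidelity_mode = c("faithful", "explorer"),
                       transit_speed = 6,
                       forage_speed = 1.5,
                       transit_turn_sd = 10,
                       forage_pull_km = 3,
                       step_min = 10,
                       truncation_prob = 0.10,
                       truncation_fraction = 0.80,
                       nest_check_interval_h = 2.5,
                       dup_prob = 0.05,
                       spike_prob = 0.05,
                       ice_south_sic = 20,
                       ice_north_sic = 95,
                       ice_recession_per_day = 0.02,
                       ice_noise_sd = 2,
                       ice_cell_km = 6.25,
                       max_range_km = 150,
                       seed = 1) {
  fidelity_mode <- match.arg(fidelity_mode)
  f <- phase_fractions_true
  stopifnot(n_birds >= 1, f[1] > 0, f[2] > f[1], f[2] < 100,
            heading_between_sd >= 0, heading_within_sd >= 0,
            logdist_between_sd >= 0, logdist_within_sd >= 0,
            truncation_prob >= 0, truncation_prob <= 1,
            truncation_fraction > 0, truncation_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

# Trip-count distribution of the reference cohort (individuals per 2..9
# trips); used when trips_per_bird is NULL.
.TRIP_COUNT_WEIGHTS <- c(`2` = 76, `3` = 21, `4` = 12, `5` = 11,
                         `6` = 1, `7` = 2, `8` = 3, `9` = 3)

.season_peak_hatch <- function(season) {
  as.Date(paste0(substr(season, 1, 4), "-12-20"))
}

# One three-phase trip as a correlated walk toward/around/back from a patch.
.simulate_trip_walk <- function(patch_xy, total_h, t0, cfg) {
  f1 <- cfg$phase_fractions_true[1] / 100
  f2 <- cfg$phase_fractions_true[2] / 100
  dt_grid <- cfg$step_min / 60
  # the device grid plus the exact arrival time, so the final (possibly
  # short) step closes at the planned speed rather than an inflated one
  times_h <- unique(c(seq(0, total_h, by = dt_grid), total_h))
  n <- length(times_h)
  x <- y <- numeric(n)
  rad <- pi / 180
  for (i in 2:n) {
    dt_h <- times_h[i] - times_h[i - 1]
    el <- times_h[i - 1] / total_h
    px <- patch_xy[1] - x[i - 1]; py <- patch_xy[2] - y[i - 1]
    if (el < f1) {                      # outbound: toward the patch
      ang <- atan2(py, px) + stats::rnorm(1, 0, cfg$transit_turn_sd) * rad
      sp <- cfg$transit_speed
    } else if (el <= f2) {              # central: tortuous, mean-reverting
      d_patch <- sqrt(px^2 + py^2)
      # beyond ~1/3 of the patch scale the heading is biased back toward the
      # patch centre (wide angular noise keeps the walk tortuous); closer in
      # it is fully random, giving a stationary cloud at the patch
      ang <- if (d_patch > cfg$forage_pull_km / 3)
        atan2(py, px) + stats::rnorm(1, 0, 60) * rad
      else stats::runif(1, 0, 2 * pi)
      sp <- cfg$forage_speed
    } else {                            # inbound: home in time to arrive at T
      t_left <- total_h - times_h[i - 1]
      d_col <- sqrt(x[i - 1]^2 + y[i - 1]^2)
      v_req <- d_col / t_left
      # on schedule: noisy heading at the required speed; behind schedule:
      # straight to the colony, so closure is exact and the final approach
      # never implies a speed the QC filter would reject
      if (v_req > cfg$transit_speed) {
        ang <- atan2(-y[i - 1], -x[i - 1])
      } else {
        ang <- atan2(-y[i - 1], -x[i - 1]) +
          stats::rnorm(1, 0, cfg$transit_turn_sd) * rad
      }
      sp <- min(v_req, cfg$transit_speed * 1.5)
    }
    step <- sp * dt_h
    if (el > f2) step <- min(step, sqrt(x[i - 1]^2 + y[i - 1]^2))
    x[i] <- x[i - 1] + step * cos(ang)
    y[i] <- y[i - 1] + step * sin(ang)
  }
  x[n] <- 0; y[n] <- 0                  # lands at the colony
  ll <- .xy_to_lonlat(x, y, c(140.01, -66.66))
  data.frame(timestamp = t0 + times_h * 3600, lon = ll$lon, lat = ll$lat)
}

#' Simulate a full tracking cohort with known truth
#'
#' Generates every input the analysis pipeline consumes — raw multi-trip GPS
#' tracks (with injected duplicates, teleport spikes and truncated
#' recordings), nest-check return times, per-season peak-hatch dates — plus
#' the truth record: per-bird trait values, per-trip phase-boundary times and
#' patch centres, and the true repeatability of each trait.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort`: `tracks` (data.frame in the raw track
#'   CSV layout), `nest_checks`, `peak_hatch` (named Date vector by season),
#'   `truth` (`birds`, `trips`, `true_R`, `config`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  colony <- c(140.01, -66.66)
  seasons <- rep(cfg$seasons, length.out = cfg$n_birds)
  shift <- cfg$season_shift
  if (is.null(shift)) shift <- stats::setNames(rep(0, length(cfg$seasons)),
                                               cfg$seasons)
  n_trips <- if (is.null(cfg$trips_per_bird)) {
    sample(as.integer(names(.TRIP_COUNT_WEIGHTS)), cfg$n_birds, replace = TRUE,
           prob = .TRIP_COUNT_WEIGHTS)
  } else rep(cfg$trips_per_bird, length.out = cfg$n_birds)
  peak_hatch <- stats::setNames(.season_peak_hatch(unique(seasons)),
                                unique(seasons))
  b_head <- stats::rnorm(cfg$n_birds, 0, cfg$heading_between_sd)
  b_dist <- stats::rnorm(cfg$n_birds, 0, cfg$logdist_between_sd)
  tracks <- list(); checks <- list(); truth_trips <- list()
  for (b in seq_len(cfg$n_birds)) {
    id <- sprintf("bird%03d", b)
    season <- seasons[b]
    ph <- peak_hatch[[season]]
    t_cursor <- as.POSIXct(ph, tz = "UTC") +
      stats::runif(1, 0, 5) * 86400
    dep_fixes <- list()
    for (j in seq_len(n_trips[b])) {
      if (cfg$fidelity_mode == "faithful") {
        head_j <- cfg$heading_mean + b_head[b] +
          stats::rnorm(1, 0, cfg$heading_within_sd)
        ld_j <- cfg$logdist_mean + shift[[season]] + b_dist[b] +
          stats::rnorm(1, 0, cfg$logdist_within_sd)
      } else {  # explorer: fresh population draw, no individual component
        head_j <- cfg$heading_mean +
          stats::rnorm(1, 0, sqrt(cfg$heading_between_sd^2 +
                                    cfg$heading_within_sd^2))
        ld_j <- cfg$logdist_mean + shift[[season]] +
          stats::rnorm(1, 0, sqrt(cfg$logdist_between_sd^2 +
                                    cfg$logdist_within_sd^2))
      }
      # tail draws beyond the feasible foraging range are redrawn (real birds
      # cannot outrun the colony-return constraint); a configuration whose
      # draws are persistently out of range is rejected outright
      tries <- 0L
      while (exp(ld_j) > cfg$max_range_km && tries < 100L) {
        ld_j <- if (cfg$fidelity_mode == "faithful")
          cfg$logdist_mean + shift[[season]] + b_dist[b] +
            stats::rnorm(1, 0, cfg$logdist_within_sd)
        else cfg$logdist_mean + shift[[season]] +
          stats::rnorm(1, 0, sqrt(cfg$logdist_between_sd^2 +
                                    cfg$logdist_within_sd^2))
        tries <- tries + 1L
      }
      D <- exp(ld_j)
      if (D > cfg$max_range_km)
        stop("infeasible geometry: patch at ", round(D),
             " km exceeds max_range_km")
      # bearing 0 = north, positive eastward -> planar angle from east axis
      ang <- (90 - head_j) * pi / 180
      patch_xy <- D * c(cos(ang), sin(ang))
      f1 <- cfg$phase_fractions_true[1] / 100
      # effective transit straightness E[cos(noise)] for N(0, turn_sd) headings
      straight <- exp(-(cfg$transit_turn_sd * pi / 180)^2 / 2)
      total_h <- D / (cfg$transit_speed * straight) / f1
      walk <- .simulate_trip_walk(patch_xy, total_h, t_cursor, cfg)
      t_ret_true <- walk$timestamp[nrow(walk)]
      truncated <- stats::runif(1) < cfg$truncation_prob
      if (truncated) {
        keep <- walk$timestamp <= t_cursor + cfg$truncation_fraction *
          total_h * 3600
        walk <- walk[keep, , drop = FALSE]
      }
      if (stats::runif(1) < cfg$dup_prob && nrow(walk) > 4) {
        i <- sample(2:(nrow(walk) - 1), 1)
        walk <- rbind(walk[1:i, ], walk[i, ], walk[(i + 1):nrow(walk), ])
      }
      if (stats::runif(1) < cfg$spike_prob && nrow(walk) > 6) {
        i <- sample(3:(nrow(walk) - 2), 1)
        walk$lon[i] <- walk$lon[i] + 1.0   # ~45 km teleport at 66.66 S
      }
      obs_ret <- t_ret_true + stats::runif(1, 0, cfg$nest_check_interval_h * 3600)
      checks[[length(checks) + 1L]] <- data.frame(
        bird_id = id, season = season, trip_index = j,
        observed_return = format(obs_ret, "%Y-%m-%dT%H:%M:%S"))
      pxy <- .xy_to_lonlat(patch_xy[1], patch_xy[2], colony)
      truth_trips[[length(truth_trips) + 1L]] <- data.frame(
        bird_id = id, season = season, trip_index = j,
        departure = t_cursor,
        t_f1 = t_cursor + f1 * total_h * 3600,
        t_f2 = t_cursor + cfg$phase_fractions_true[2] / 100 * total_h * 3600,
        return_true = t_ret_true,
        patch_lon = pxy$lon, patch_lat = pxy$lat,
        true_duration_h = total_h, true_max_km = D, true_heading = head_j,
        truncated = truncated)
      if (truncated) {
        # logger stopped at sea: nothing more is recorded for this bird
        dep_fixes[[j]] <- walk
        break
      }
      # colony dwell between trips: a few fixes at the nest
      dwell_h <- stats::runif(1, 4, 10)
      dwell_t <- t_ret_true + c(0.2, 0.5, 0.8) * dwell_h * 3600
      dep_fixes[[j]] <- rbind(walk, data.frame(
        timestamp = dwell_t, lon = colony[1], lat = colony[2]))
      t_cursor <- t_ret_true + dwell_h * 3600
    }
    fixes <- do.call(rbind, dep_fixes)
    tracks[[b]] <- data.frame(bird_id = id, season = season,
                              timestamp = format(fixes$timestamp,
                                                 "%Y-%m-%dT%H:%M:%S"),
                              lon = fixes$lon, lat = fixes$lat)
  }
  prop_A <- function(b2, w2) if (b2 + w2 == 0) NA_real_ else b2 / (b2 + w2)
  true_R <- if (cfg$fidelity_mode == "faithful") {
    list(log_max_distance = prop_A(cfg$logdist_between_sd^2,
                                   cfg$logdist_within_sd^2),
         heading = prop_A(cfg$heading_between_sd^2, cfg$heading_within_sd^2))
  } else list(log_max_distance = 0, heading = 0)
  structure(list(
    tracks = do.call(rbind, tracks),
    nest_checks = do.call(rbind, checks),
    peak_hatch = peak_hatch,
    truth = list(birds = data.frame(bird_id = sprintf("bird%03d",
                                                      seq_len(cfg$n_birds)),
                                    season = seasons,
                                    b_heading = b_head, b_logdist = b_dist),
                 trips = do.call(rbind, truth_trips),
                 true_R = true_R,
                 config = cfg)),
    class = "sim_cohort")
}

#' Write a simulated cohort to CSV files
#'
#' Emits exactly the formats the ingestion functions consume: `tracks.csv`,
#' `nest_checks.csv`, `peak_hatch.csv`, plus the truth table
#' (`truth_trips.csv`, `truth_birds.csv`, `truth.json`).
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(sim$nest_checks, file.path(dir, "nest_checks.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(season = names(sim$peak_hatch),
                              peak_hatch = format(sim$peak_hatch)),
                   file.path(dir, "peak_hatch.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$trips, file.path(dir, "truth_trips.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$birds, file.path(dir, "truth_birds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(true_R = sim$truth$true_R,
                            seed = sim$truth$config$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Build deployment objects from a simulated cohort without file I/O
#'
#' @param sim A `sim_cohort`.
#' @return List of deployments, as [read_tracks()] would return after writing
#'   and re-reading the tracks.
#' @export
cohort_deployments <- function(sim) {
  tr <- sim$tracks
  ts <- .parse_utc(tr$timestamp)
  key <- paste(tr$bird_id, tr$season, sep = "\r")
  unname(lapply(split(seq_len(nrow(tr)), factor(key, levels = unique(key))),
                function(i) {
                  .new_deployment(tr$bird_id[i[1]], tr$season[i[1]],
                                  data.frame(timestamp = ts[i],
                                             lon = tr$lon[i], lat = tr$lat[i]))
                }))
}

#' Simulate daily sea-ice fields over the study area
#'
#' Day 0 is a clipped latitudinal gradient (more ice offshore/north) plus a
#' smooth low-frequency noise surface; each subsequent day is the previous
#' day times `(1 - recession rate)` plus fresh smooth noise, clipped to
#' [0, 100]. Cells within 5 km of the colony are masked as land.
#'
#' @param cfg A [sim_config()].
#' @param dates Date vector of required days.
#' @return List of `ice_field`s named by date.
#' @export
simulate_icefields <- function(cfg = sim_config(), dates) {
  set.seed(cfg$seed + 1L)
  dates <- sort(as.Date(dates))
  colony <- c(140.01, -66.66)
  dlat <- cfg$ice_cell_km / .KM_PER_DEG_LAT
  dlon <- cfg$ice_cell_km / (.KM_PER_DEG_LAT * cos(colony[2] * pi / 180))
  lat <- seq(-67 + dlat / 2, -64, by = dlat)
  lon <- seq(137 + dlon / 2, 143, by = dlon)
  cc <- expand.grid(lat = lat, lon = lon)  # row-major like the grid matrix
  base <- cfg$ice_south_sic +
    (cc$lat + 67) / 3 * (cfg$ice_north_sic - cfg$ice_south_sic)
  smooth_noise <- function() {
    if (cfg$ice_noise_sd == 0) return(0)
    ph <- stats::runif(4, 0, 2 * pi)
    cfg$ice_noise_sd * sqrt(2) *
      sin(2 * pi * (cc$lon - 137) / stats::runif(1, 2, 6) + ph[1]) *
      sin(2 * pi * (cc$lat + 67) / stats::runif(1, 1, 3) + ph[2])
  }
  land <- great_circle_km(cc$lon, cc$lat, colony[1], colony[2]) < 5
  vals <- pmin(pmax(base + smooth_noise(), 0), 100)
  fields <- list()
  for (i in seq_along(dates)) {
    if (i > 1) {
      gap <- as.numeric(dates[i] - dates[i - 1])  # calendar days elapsed
      vals <- pmin(pmax(vals * (1 - cfg$ice_recession_per_day)^gap +
                          smooth_noise(), 0), 100)
    }
    g <- matrix(vals, length(lat), length(lon))
    g[matrix(land, length(lat), length(lon))] <- NA
    fields[[format(dates[i])]] <- ice_field(dates[i], cfg$ice_cell_km,
                                            lon, lat, g)
  }
  fields
}

#' Simulate a balanced trait table with known variance components
#'
#' Direct generator of the variance structure the repeatability estimator
#' targets: `y = mu + season effect + bird effect + residual`, with bird
#' effects N(0, between_sd^2) and residuals N(0, within_sd^2), so the true
#' repeatability is `between_sd^2 / (between_sd^2 + within_sd^2)`. Birds are
#' split evenly across seasons (each bird in one season, as in multi-year
#' tracking cohorts); the timing covariate is drawn uniformly and has no
#' effect unless `timing_slope` is set.
#'
#' @param n_birds,n_trips Birds and trips per bird.
#' @param between_sd,within_sd Trait SD components.
#' @param mu Grand mean.
#' @param seasons Season labels (default one season).
#' @param season_shift Optional numeric vector of per-season additive shifts
#'   (recycled over `seasons`).
#' @param timing_slope Effect of `days_since_peak_hatch` on the trait.
#' @param seed Integer seed.
#' @return data.frame: `bird_id`, `season`, `days_since_peak_hatch`, `y`,
#'   with the true R in attribute `true_R`.
#' @export
simulate_trait_data <- function(n_birds, n_trips, between_sd, within_sd,
                                mu = 0, seasons = "2015-16",
                                season_shift = NULL, timing_slope = 0,
                                seed = 1) {
  set.seed(seed)
  season <- rep(rep(seasons, length.out = n_birds), each = n_trips)
  shift <- if (is.null(season_shift)) rep(0, length(seasons)) else
    rep(season_shift, length.out = length(seasons))
  names(shift) <- seasons
  bird <- rep(sprintf("bird%03d", seq_len(n_birds)), each = n_trips)
  b <- rep(stats::rnorm(n_birds, 0, between_sd), each = n_trips)
  timing <- stats::runif(n_birds * n_trips, -5, 25)
  y <- mu + shift[season] + b + timing_slope * timing +
    stats::rnorm(n_birds * n_trips, 0, within_sd)
  out <- data.frame(bird_id = bird, season = season,
                    days_since_peak_hatch = timing, y = unname(y))
  attr(out, "true_R") <- if (between_sd + within_sd == 0) NA_real_ else
    between_sd^2 / (between_sd^2 + within_sd^2)
  out
}
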