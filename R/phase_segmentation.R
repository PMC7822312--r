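# Pooled three-segment (two-changepoint) segmentation of the normalized
# distance-time profile, and extraction of the central foraging phase.
#
# Trips of a central-place forager trace a bell on (elapsed duration %,
# % of maximal colony distance): outbound rise, central plateau, inbound
# fall. A continuous piecewise-linear model with two breakpoints is fitted
# to the pooled profile by exhaustive least-squares grid search; the two
# fitted fractions cut every trip into outbound / central / inbound.

#' Phase model: two breakpoint fractions of trip duration
#'
#' @param f1,f2 Breakpoints in percent of elapsed trip duration,
#'   `0 < f1 < f2 < 100`. The defaults are the population-level values
#'   calibrated on the original chick-rearing tracking cohort.
#' @param uncertainty Optional named vector of half-widths for `f1`, `f2`.
#' @param fit_score Residual sum of squares of the fit (NA for fixed models).
#' @return List of class `phase_model`.
#' @export
phase_model <- function(f1 = 31.2, f2 = 69.7, uncertainty = c(f1 = NA, f2 = NA),
                        fit_score = NA_real_) {
  stopifnot(f1 >= 0, f2 > f1, f2 <= 100)  # fitted models have 0 < f1 < f2 < 100
  structure(list(f1 = f1, f2 = f2, uncertainty = uncertainty,
                 fit_score = fit_score),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("<phase model: breakpoints %.1f%% and %.1f%% of trip duration>\n",
              x$f1, x$f2))
  invisible(x)
}

#' Pool trips onto the normalized distance-time profile
#'
#' For every fix of every trip: elapsed time as a percent of total trip
#' duration, and straight-line colony distance as a percent of the trip's
#' maximal distance (100 at the most distal fix). Trips whose maximal
#' distance is zero are excluded with a message.
#'
#' @param trips List of resampled trips.
#' @param p [qc_params()] (colony location).
#' @return data.frame: trip keys, `pct_duration`, `pct_maxdist`.
#' @export
normalize_trips <- function(trips, p = qc_params()) {
  out <- lapply(trips, function(t) {
    fx <- t$fixes
    dur <- as.numeric(difftime(t$return_time, t$departure, units = "secs"))
    d <- great_circle_km(fx$lon, fx$lat, p$colony[1], p$colony[2])
    if (max(d) <= 0) {
      message("trip ", t$bird_id, "#", t$trip_index,
              ": zero maximal distance; excluded from profile")
      return(NULL)
    }
    data.frame(bird_id = t$bird_id, season = t$season, trip_index = t$trip_index,
               pct_duration = 100 *
                 as.numeric(difftime(fx$timestamp, t$departure, units = "secs")) / dur,
               pct_maxdist = 100 * d / max(d))
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Fit a continuous two-changepoint piecewise-linear model to a profile
#'
#' Exhaustive least-squares search over a regular grid of breakpoint pairs
#' `(f1, f2)`, `f1 < f2`, for the continuous three-segment linear model of
#' `pct_maxdist` on `pct_duration` (hinge basis `1, x, (x-f1)+, (x-f2)+`).
#' Per-breakpoint uncertainty is the half-width of the interval over which
#' the profiled residual sum of squares stays within 5% of its minimum.
#'
#' @param profile data.frame from [normalize_trips()] (columns `pct_duration`,
#'   `pct_maxdist`). All fixes are weighted equally.
#' @param grid_step Breakpoint grid step, percent (default 0.5).
#' @return A `phase_model` with fitted `f1`, `f2`, `uncertainty`, `fit_score`.
#' @export
fit_three_segment <- function(profile, grid_step = 0.5) {
  x <- profile$pct_duration
  y <- profile$pct_maxdist
  stopifnot(length(x) >= 3 / grid_step)
  if (stats::sd(y) == 0) stop("no bell structure: profile is constant")
  cand <- seq(grid_step, 100 - grid_step, by = grid_step)
  K <- length(cand)
  # Hinge columns and the cross-moments needed for 4x4 normal equations.
  H <- vapply(cand, function(f) pmax(x - f, 0), numeric(length(x)))
  n <- length(x)
  Sx <- sum(x); Sxx <- sum(x * x); Sy <- sum(y); Sxy <- sum(x * y)
  Syy <- sum(y * y)
  Sh <- colSums(H); Shx <- colSums(H * x); Shy <- colSums(H * y)
  Shh <- crossprod(H)
  rss <- matrix(Inf, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      XtX <- matrix(c(n, Sx, Sh[i], Sh[j],
                      Sx, Sxx, Shx[i], Shx[j],
                      Sh[i], Shx[i], Shh[i, i], Shh[i, j],
                      Sh[j], Shx[j], Shh[i, j], Shh[j, j]), 4, 4)
      Xty <- c(Sy, Sxy, Shy[i], Shy[j])
      b <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
      if (!is.null(b)) rss[i, j] <- max(Syy - sum(b * Xty), 0)
    }
  }
  best <- arrayInd(which.min(rss), dim(rss))
  min_rss <- rss[best[1], best[2]]
  prof1 <- apply(rss, 1, min)  # profile over f1 (minimized over f2)
  prof2 <- apply(rss, 2, min)
  in1 <- cand[prof1 <= 1.05 * min_rss]
  in2 <- cand[prof2 <= 1.05 * min_rss]
  phase_model(f1 = cand[best[1]], f2 = cand[best[2]],
              uncertainty = c(f1 = diff(range(in1)) / 2,
                              f2 = diff(range(in2)) / 2),
              fit_score = min_rss)
}

.pct_duration <- function(t) {
  dur <- as.numeric(difftime(t$return_time, t$departure, units = "secs"))
  100 * as.numeric(difftime(t$fixes$timestamp, t$departure, units = "secs")) / dur
}

#' Extract the central (foraging) phase of a trip
#'
#' Fixes with elapsed-duration percentage in `[f1, f2]` (boundary fixes
#' included). Segments with fewer than two fixes are flagged as too short for
#' fidelity analysis via the `too_short` attribute.
#'
#' @param t A resampled trip.
#' @param m A `phase_model`.
#' @return data.frame of central-phase fixes with attribute `too_short`.
#' @export
extract_central_phase <- function(t, m = phase_model()) {
  pd <- .pct_duration(t)
  seg <- t$fixes[pd >= m$f1 & pd <= m$f2, , drop = FALSE]
  rownames(seg) <- NULL
  attr(seg, "too_short") <- nrow(seg) < 2
  seg
}

#' Compare per-phase kinematics across trips
#'
#' Assigns every fix to outbound / central / inbound by the phase model,
#' computes [segment_kinematics()] per trip and phase, and tests the central
#' phase against each transit phase with Wilcoxon rank-sum tests on distance,
#' mean speed and sinuosity. Foraging concentrated in the central phase shows
#' as shorter distances, slower speeds and higher sinuosity there.
#'
#' @param trips List of resampled trips (>= 2 for tests; with a single trip
#'   only the descriptive table is returned, with a warning).
#' @param m A `phase_model`.
#' @return List with `kinematics` (one row per trip x phase) and `tests`
#'   (one row per phase contrast x variable, with the effect direction), the
#'   latter `NULL` when only one trip is supplied.
#' @export
validate_phases <- function(trips, m = phase_model()) {
  kin <- do.call(rbind, lapply(trips, function(t) {
    pd <- .pct_duration(t)
    phase <- cut(pd, c(-Inf, m$f1, m$f2, Inf),
                 labels = c("outbound", "central", "inbound"), right = FALSE)
    phase[pd >= m$f1 & pd <= m$f2] <- "central"  # boundaries belong to central
    do.call(rbind, lapply(levels(phase), function(ph) {
      fx <- t$fixes[phase == ph, , drop = FALSE]
      if (nrow(fx) < 2) return(NULL)
      cbind(data.frame(bird_id = t$bird_id, season = t$season,
                       trip_index = t$trip_index, phase = ph),
            segment_kinematics(fx))
    }))
  }))
  if (length(trips) < 2) {
    warning("single trip: descriptive kinematics only, no phase tests")
    return(list(kinematics = kin, tests = NULL))
  }
  vars <- c("distance", "mean_speed", "sinuosity")
  tests <- do.call(rbind, lapply(c("outbound", "inbound"), function(other) {
    do.call(rbind, lapply(vars, function(v) {
      a <- kin[kin$phase == "central", v]
      b <- kin[kin$phase == other, v]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2 ||
          (length(unique(c(a, b))) < 2)) {
        return(data.frame(contrast = paste0("central vs ", other), variable = v,
                          central_median = stats::median(a),
                          transit_median = stats::median(b),
                          direction = "null", p_value = NA_real_))
      }
      w <- suppressWarnings(stats::wilcox.test(a, b))
      med_a <- stats::median(a); med_b <- stats::median(b)
      data.frame(contrast = paste0("central vs ", other), variable = v,
                 central_median = med_a, transit_median = med_b,
                 direction = if (w$p.value >= 0.05 || med_a == med_b) "null"
                             else if (med_a < med_b) "lower" else "higher",
                 p_value = w$p.value)
    }))
  }))
  list(kinematics = kin, tests = tests)
}
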