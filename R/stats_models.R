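# Inference on the fidelity table: year effects on log NND, year x timing
# models with Tukey-adjusted pairwise year contrasts, and penalized-spline
# smooths of log NND on sea-ice covariates with an individual random effect.

.coef_table <- function(fit) {
  ct <- summary(fit)$coefficients
  data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
             t = ct[, 3], p_value = round(ct[, 4], 3), row.names = NULL)
}

#' Year effect on log NND
#'
#' Linear model of log(NND) on year (categorical, first season as the
#' reference level).
#'
#' @param records Fidelity table from [fidelity_table()] (>= 2 seasons).
#' @return List of class `nnd_model_result`: `coefficients` (term, estimate,
#'   SE, t, p), `reference` season, `model`.
#' @export
fit_year_model <- function(records) {
  records$season <- factor(records$season)
  if (nlevels(records$season) < 2) stop("need at least 2 seasons")
  fit <- stats::lm(log(nnd) ~ season, data = records)
  structure(list(coefficients = .coef_table(fit),
                 reference = levels(records$season)[1],
                 transform = "log", model = fit),
            class = "nnd_model_result")
}

#' @export
print.nnd_model_result <- function(x, ...) {
  cat("log(NND) model (reference ", x$reference, "):\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Year x season-timing effects on log NND with pairwise year contrasts
#'
#' Fits `log(nnd) ~ year * days_since_peak_hatch`, evaluates estimated
#' marginal means per year at the grand-mean timing, and reports all pairwise
#' year differences with Tukey adjustment, plus per-year timing slopes.
#' Seasons with fewer than 3 records are dropped from the contrasts.
#'
#' @param records Fidelity table with `days_since_peak_hatch` spread.
#' @return List of class `nnd_model_result` plus `emmeans` (per-year marginal
#'   means), `contrasts` (Tukey-adjusted pairs) and `slopes` (per-year
#'   timing trends).
#' @export
fit_year_timing_model <- function(records) {
  records$season <- factor(records$season)
  if (nlevels(records$season) < 2) stop("need at least 2 seasons")
  small <- names(which(table(records$season) < 3))
  if (length(small) > 0) {
    message("season(s) dropped from contrasts (fewer than 3 records): ",
            paste(small, collapse = ", "))
    records <- droplevels(records[!records$season %in% small, , drop = FALSE])
  }
  fit <- stats::lm(log(nnd) ~ season * days_since_peak_hatch, data = records)
  emm <- emmeans::emmeans(fit, "season",
                          at = list(days_since_peak_hatch =
                                      mean(records$days_since_peak_hatch)))
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  slopes <- as.data.frame(
    emmeans::emtrends(fit, "season", var = "days_since_peak_hatch"))
  structure(list(coefficients = .coef_table(fit),
                 reference = levels(records$season)[1],
                 transform = "log", model = fit,
                 emmeans = as.data.frame(emm),
                 contrasts = prs, slopes = slopes),
            class = "nnd_model_result")
}

#' Smooth effect of a sea-ice covariate on log NND
#'
#' Penalized cubic-spline smooth of log(NND) on `mean_sic_pair` or
#' `sic_difference`, with a bird-level random intercept; the smoothing
#' parameter is chosen by REML. The fitted curve (with a 95% band, random
#' effect excluded) is exported on a 100-point covariate grid, on the log
#' scale and back-transformed. With too few distinct covariate values for
#' the spline basis the model falls back to a linear term (flagged).
#'
#' @param records Fidelity table (>= 30 records; covariate spread over more
#'   than 5 percentage points).
#' @param covariate `"mean_sic_pair"` or `"sic_difference"`.
#' @param k Spline basis dimension (default 10).
#' @return List of class `smooth_fit_result`: `curve` (grid, fit, band, both
#'   scales), `edf`, `random_intercept_sd`, `linear_fallback`, `model`.
#' @export
fit_smooth_ice_model <- function(records,
                                 covariate = c("mean_sic_pair", "sic_difference"),
                                 k = 10) {
  covariate <- match.arg(covariate)
  x <- records[[covariate]]
  if (is.null(x)) stop("records lack covariate ", covariate)
  stopifnot(nrow(records) >= 30)
  if (diff(range(x)) <= 5)
    stop("covariate spread must exceed 5 percentage points")
  d <- data.frame(.y = log(records$nnd), .x = x,
                  bird_id = factor(records$bird_id))
  fallback <- length(unique(x)) < k + 2
  if (fallback) {
    message("too few distinct covariate values for a spline basis; linear term used")
    fit <- mgcv::gam(.y ~ .x + s(bird_id, bs = "re"), data = d, method = "REML")
  } else {
    fit <- mgcv::gam(.y ~ s(.x, bs = "cs", k = k) + s(bird_id, bs = "re"),
                     data = d, method = "REML")
  }
  grid <- data.frame(.x = seq(min(x), max(x), length.out = 100),
                     bird_id = d$bird_id[1])
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE,
                          exclude = "s(bird_id)", newdata.guaranteed = TRUE)
  sm <- summary(fit)
  edf <- if (fallback) 1 else unname(sm$edf[1])
  re_var <- mgcv::gam.vcomp(fit)
  re_sd <- re_var[grep("bird_id", rownames(re_var)), "std.dev"][1]
  curve <- data.frame(covariate = grid$.x,
                      fit_log = as.numeric(pr$fit),
                      lo_log = as.numeric(pr$fit - 1.96 * pr$se.fit),
                      hi_log = as.numeric(pr$fit + 1.96 * pr$se.fit))
  curve$fit_km <- exp(curve$fit_log)
  curve$lo_km <- exp(curve$lo_log)
  curve$hi_km <- exp(curve$hi_log)
  structure(list(covariate = covariate, curve = curve, edf = edf,
                 random_intercept_sd = unname(re_sd),
                 linear_fallback = fallback, model = fit),
            class = "smooth_fit_result")
}

#' @export
print.smooth_fit_result <- function(x, ...) {
  cat(sprintf("<smooth log(NND) ~ s(%s): edf %.2f%s, bird SD %.3f>\n",
              x$covariate, x$edf,
              if (x$linear_fallback) " (linear fallback)" else "",
              x$random_intercept_sd))
  invisible(x)
}
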