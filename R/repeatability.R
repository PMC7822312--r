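# Population-level repeatability of trip traits via Gaussian random-intercept
# mixed models: R = sigma2_A / (sigma2_A + sigma2), where sigma2_A is the
# between-individual variance and sigma2 the residual (within-individual)
# variance. Fixed-effect structures (year, season timing, their interaction)
# are selected backwards by AIC; "adjusted" repeatability conditions on the
# selected fixed effects, "non-adjusted" uses the intercept-only model.

.TERMS_MAP <- c(year = "season", timing = "days_since_peak_hatch",
                "year:timing" = "season:days_since_peak_hatch")

#' Specify a trait mixed model
#'
#' @param response Name of the trait column in the trip table.
#' @param fixed Subset of `c("year", "timing", "year:timing")`; the
#'   interaction requires both main effects.
#' @param transform `"log"` or `"identity"`. Durations and distances are
#'   log-transformed for normality; bearing is not.
#' @return List of class `lmm_spec`.
#' @export
lmm_spec <- function(response,
                     fixed = c("year", "timing", "year:timing"),
                     transform = c("log", "identity")) {
  transform <- match.arg(transform)
  stopifnot(all(fixed %in% names(.TERMS_MAP)))
  if ("year:timing" %in% fixed && !all(c("year", "timing") %in% fixed))
    stop("interaction requires both main effects")
  structure(list(response = response, fixed = fixed, transform = transform),
            class = "lmm_spec")
}

.lmm_formula <- function(spec) {
  rhs <- if (length(spec$fixed) == 0) "1" else
    paste(.TERMS_MAP[spec$fixed], collapse = " + ")
  stats::as.formula(paste(".y ~", rhs, "+ (1 | bird_id)"))
}

.prep_lmm_data <- function(spec, data) {
  y <- data[[spec$response]]
  if (spec$transform == "log") y <- log(y)
  if (any(!is.finite(y))) stop("response not finite after transform")
  data$.y <- y
  data$season <- factor(data$season)
  data$bird_id <- factor(data$bird_id)
  data
}

#' Fit a Gaussian random-intercept mixed model for one trait
#'
#' Variance components come from the REML fit; a maximum-likelihood refit
#' provides the AIC used for fixed-structure comparison.
#'
#' @param spec An [lmm_spec()].
#' @param data Trip table with columns `bird_id`, `season`,
#'   `days_since_peak_hatch` and the response.
#' @return List of class `lmm_fit`: `sigma2_A`, `sigma2`, `aic` (ML),
#'   `logLik` (REML), `converged`, the REML `model`, and the `spec`.
#' @export
fit_lmm <- function(spec, data) {
  data <- .prep_lmm_data(spec, data)
  tab <- table(data$bird_id)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 individuals with at least 2 trips each")
  form <- .lmm_formula(spec)
  conv <- TRUE
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(form, data = data, REML = TRUE)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        conv <<- FALSE
      invokeRestart("muffleWarning")
    })
  fit_ml <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = data, REML = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    sigma2_A = vc$vcov[vc$grp == "bird_id"],
    sigma2 = vc$vcov[vc$grp == "Residual"],
    fixef = lme4::fixef(fit),
    aic = stats::AIC(fit_ml),
    logLik = as.numeric(stats::logLik(fit)),
    converged = conv,
    model = fit,
    spec = spec,
    n_obs = nrow(data), n_birds = nlevels(data$bird_id)),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm %s(%s) ~ %s: sigma2_A %.3g, sigma2 %.3g, AIC(ML) %.1f>\n",
              x$spec$transform, x$spec$response,
              if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ")
              else "1",
              x$sigma2_A, x$sigma2, x$aic))
  invisible(x)
}

.droppable <- function(fixed) {
  if ("year:timing" %in% fixed) return("year:timing")
  fixed
}

#' Backward AIC selection of the fixed-effect structure
#'
#' Starting from the full year x timing interaction model, terms are dropped
#' along the hierarchy (interaction, then main effects, down to intercept
#' only). At each step the drop giving the lowest maximum-likelihood AIC is
#' considered; the smaller model is kept unless the larger model's AIC is
#' better by more than 2.
#'
#' @param spec Starting [lmm_spec()] (normally the full model).
#' @param data Trip table (see [fit_lmm()]).
#' @return The selected `lmm_fit` (REML variance components).
#' @export
select_fixed_effects <- function(spec, data) {
  if (length(unique(data$season)) < 2 &&
      any(c("year", "year:timing") %in% spec$fixed)) {
    message("single season: year terms dropped from the candidate structure")
    spec$fixed <- setdiff(spec$fixed, c("year", "year:timing"))
  }
  current <- fit_lmm(spec, data)
  repeat {
    drops <- .droppable(current$spec$fixed)
    if (length(drops) == 0) break
    cands <- lapply(drops, function(d) {
      s <- current$spec
      s$fixed <- setdiff(s$fixed, d)
      tryCatch(fit_lmm(s, data), error = function(e) NULL)
    })
    cands <- cands[!vapply(cands, is.null, TRUE)]
    cands <- cands[vapply(cands, function(f) isTRUE(f$converged), TRUE)]
    if (length(cands) == 0) break
    best <- cands[[which.min(vapply(cands, `[[`, 0, "aic"))]]
    # keep the smaller model unless the larger wins by more than 2 AIC units
    if (best$aic <= current$aic + 2) current <- best else break
  }
  current
}

#' Repeatability from a fitted trait model
#'
#' `R = sigma2_A / (sigma2_A + sigma2)`, classified as low (R < 0.25),
#' moderate (0.25 <= R <= 0.5) or high (R > 0.5).
#'
#' @param fit An `lmm_fit`.
#' @return List of class `repeatability_result`: `R`, `category`,
#'   `sigma2_A`, `sigma2`, `adjusted` flag (any fixed effects present).
#' @export
repeatability <- function(fit) {
  tot <- fit$sigma2_A + fit$sigma2
  if (tot <= 0) stop("degenerate model: both variance components are zero")
  R <- fit$sigma2_A / tot
  structure(list(R = R,
                 category = if (R < 0.25) "low"
                            else if (R <= 0.5) "moderate" else "high",
                 sigma2_A = fit$sigma2_A, sigma2 = fit$sigma2,
                 adjusted = length(fit$spec$fixed) > 0,
                 se = NA_real_, ci = c(NA_real_, NA_real_),
                 fit = fit),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability R = %.3f%s (%s, %sadjusted)>\n", x$R,
              if (!is.na(x$se)) sprintf(" +/- %.3f", x$se) else "",
              x$category, if (x$adjusted) "" else "non-"))
  invisible(x)
}

#' Parametric-bootstrap uncertainty for repeatability
#'
#' Simulates responses from the fitted model, refits, and recomputes R.
#' The standard error is the SD of the bootstrap distribution; the interval
#' the 2.5/97.5 percentiles. Fully reproducible from `seed`.
#'
#' @param fit A converged `lmm_fit`.
#' @param n_boot Number of bootstrap draws (>= 100 for intervals, default
#'   1000; 0 returns the point estimate only).
#' @param seed Integer seed.
#' @return A `repeatability_result` with `se` and `ci` filled in and the
#'   bootstrap draws in `$boot_R`.
#' @export
bootstrap_R <- function(fit, n_boot = 1000, seed = 1) {
  res <- repeatability(fit)
  if (n_boot == 0) return(res)
  stopifnot(n_boot >= 100)
  sims <- stats::simulate(fit$model, nsim = n_boot, seed = seed)
  boot_R <- vapply(sims, function(y) {
    tryCatch({
      m <- suppressWarnings(suppressMessages(lme4::refit(fit$model, y)))
      vc <- as.data.frame(lme4::VarCorr(m))
      a <- vc$vcov[vc$grp == "bird_id"]; e <- vc$vcov[vc$grp == "Residual"]
      a / (a + e)
    }, error = function(e) NA_real_)
  }, 0)
  fail <- mean(is.na(boot_R))
  if (fail > 0.10)
    warning(sprintf("%.0f%% of bootstrap refits failed", 100 * fail))
  boot_R <- boot_R[!is.na(boot_R)]
  res$se <- stats::sd(boot_R)
  res$ci <- unname(stats::quantile(boot_R, c(0.025, 0.975)))
  res$boot_R <- boot_R
  res
}

#' Adjusted and non-adjusted repeatability for one trait
#'
#' Adjusted: the AIC-selected fixed structure. Non-adjusted: intercept-only
#' fixed structure (individual random effect only). Same response transform
#' in both.
#'
#' @param spec Starting [lmm_spec()].
#' @param data Trip table.
#' @param n_boot Bootstrap draws for each (0 = point estimates only).
#' @param seed Integer seed.
#' @return List with elements `adjusted` and `non_adjusted`
#'   (`repeatability_result`s) and `table`, a two-row data.frame.
#' @export
adjusted_vs_nonadjusted <- function(spec, data, n_boot = 0, seed = 1) {
  adj_fit <- select_fixed_effects(spec, data)
  null_spec <- spec
  null_spec$fixed <- character()
  non_fit <- fit_lmm(null_spec, data)
  adj <- bootstrap_R(adj_fit, n_boot, seed)
  non <- bootstrap_R(non_fit, n_boot, seed + 1)
  row <- function(r, f, label) data.frame(
    response = spec$response, transform = spec$transform,
    model = label, adjusted = r$adjusted,
    fixed_terms = paste(f$spec$fixed, collapse = "+"),
    R = r$R, se = r$se, ci_lo = r$ci[1], ci_hi = r$ci[2],
    sigma2_A = r$sigma2_A, sigma2 = r$sigma2, category = r$category)
  list(adjusted = adj, non_adjusted = non,
       table = rbind(row(adj, adj_fit, "adjusted"),
                     row(non, non_fit, "non_adjusted")))
}
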