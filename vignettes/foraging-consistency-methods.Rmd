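---
title: "Methods: trip segmentation, repeatability and foraging-site fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trip segmentation, repeatability and foraging-site fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tripfidelity` analyses the foraging consistency of central-place foragers —
developed around GPS-tracked Adélie penguins provisioning chicks from an
Antarctic colony — from raw multi-trip deployments through to inference on
how site fidelity responds to sea-ice conditions. This vignette documents
the models, the choices behind every tunable parameter, what the synthetic
generator does and does not emulate, and the package's known limitations.

## Track quality control

All distances are great-circle (haversine) on a sphere of radius
6371.0088 km. Cleaning removes fixes with missing timestamps or in the
Northern Hemisphere (a GPS failure mode for an Antarctic colony), exact
duplicates of (timestamp, lon, lat), and same-timestamp conflicts (first
kept, logged). The speed filter is a single forward pass anchored at the
last retained fix: a fix implying more than `speed_threshold` km/h
(default 10; these penguins swim at about 2.0 m/s = 7.2 km/h, so 10 km/h
is comfortably above sustained travel but below teleporting outliers) is
dropped and the anchor stays put. A forward pass is order-stable and
reproducible, unlike iterative global refiltering whose result can depend
on sweep order.

Trips are maximal runs of fixes outside `colony_radius` (default 0.2 km),
each bracketed by its last-inside and first-inside colony fixes. The radius
automates what field workflows do by hand when trimming colony dwell
points; it is configurable, and dwell fixes between excursions belong to no
trip. A deployment whose recording stops at sea produces a final run with
no closing colony fix: its total duration is then taken from the nest-check
return time, and the trip is kept — with a virtual colony fix appended at
the observed return — only when more than 70% of that duration was
recorded (`min_recorded_fraction = 0.70`, strictly greater-than, so
exactly 70% is discarded). Retained trips are resampled to a regular
20-minute step by linear interpolation of lon/lat in time; at these trip
scales (legs under ~100 km) the difference from great-circle interpolation
is far below the GPS noise floor, a documented approximation.

## Effort metrics

Per trip: total duration (h); total distance (cumulative great-circle km
over consecutive resampled fixes); maximal distance (straight line, colony
to the most distal fix — ties broken by the earliest fix, logged); bearing
from the colony to that distal fix (0° = north, positive eastward, range
(-180, 180]); and the timing covariate, days between departure and the
season's peak hatching date (negative for pre-peak trips). For
repeatability the bearing is folded to [0, 180] by absolute value: the
observed bearing span in this system is well under half the circle, so the
fold is injective on the data and lets a linear (non-circular) model be
used. `bearing_span_pct` documents that justification: extremes of -71.8°
and 87.8° cover 44% of the circle.

## Phase segmentation

Each fix contributes a point (x = % of trip duration elapsed, y = % of the
trip's maximal distance). Pooled over all trips, birds' out-and-back
movement traces a bell: outbound rise, central plateau near 100, inbound
fall. The package fits a continuous piecewise-linear model with two
breakpoints,

y = b0 + b1 x + b2 (x - f1)+ + b3 (x - f2)+,

minimizing the residual sum of squares over an exhaustive grid of (f1, f2)
pairs (default step 0.5%, f1 < f2). A deterministic exhaustive search was
chosen over Bayesian changepoint sampling deliberately: it is reproducible
to the bit, trivially verified against a brute-force enumeration (the test
suite does exactly that), and the grid resolution bounds the answer's
precision explicitly. Per-pair cost is kept at a 4x4 normal-equation solve
by precomputing cross-moments, so the full grid on ~5,000 pooled points
runs in seconds. Breakpoint uncertainty is reported as the half-width of
the interval over which the profiled RSS stays within 5% of its minimum —
a flat profile (poorly determined breakpoint) yields a wide interval.
Fixes are weighted equally, so long trips contribute more points than
short ones; weighting trips equally instead would require per-trip
weights, and the package documents (and tests) that the pooled fit is
invariant to trip order but not to trip duplication.

The fitted fractions cut every trip: the central phase is the closed
interval [f1, f2] of elapsed-duration percent (boundary fixes included).
`phase_model()` defaults to f1 = 31.2, f2 = 69.7 — the population-level
calibration from the original tracking cohort — for use when no pooled fit
is requested. `validate_phases` checks the biological reading: across
trips the central phase should show shorter distances, slower speeds and
higher sinuosity (path length over straight-line displacement) than either
transit phase, compared with Wilcoxon rank-sum tests.

## Sea-ice conditioning

Daily sea-ice concentration fields are regular lon/lat grids of percent
cover with an NA mask. Because this toolchain is text-only, fields are
serialized as one CSV per day with a metadata header; the container, not
the file format, carries the semantics. Extraction at a fix takes the
value of the containing cell (no interpolation), with half-open cell
ownership (west/south edges inclusive) so every point belongs to exactly
one cell. Regridding 12.5 km fields onto a 6.25 km grid assigns each fine
cell the value of its containing coarse cell — values are never invented.
`resolution_correlation` quantifies agreement between the two resolutions
along the actual tracks before committing to the finer one.

Two spatial scales condition the analyses: the fixed study rectangle
(64–67° S, 137–143° E), representing regional conditions, and the
annually prospected area — the convex hull of all retained fixes of a
season. The hull is a stated proxy for the "maximal extent" of trips; it
is conservative (no concavities) and cheap to audit. Areas are computed in
a Lambert azimuthal equal-area projection centred on the polygon; area
figures are projection-dependent and reported for description, not
inference. Regional means average unmasked cell centers inside the polygon
per day, then across days. Trip-pair covariates: `mean_sic_pair` averages
over the union of the two trips' day spans (the alternative — mean of the
two per-trip means — is exposed as `ice_mode = "mean_of_means"`), and
`sic_difference` is trip n minus trip n+1, so positive values mean the ice
receded between trips.

## Repeatability

For each trait (log total duration, log total distance, log maximal
distance, folded bearing untransformed, central-phase sea-ice
concentration), a Gaussian random-intercept model with bird identity as
the grouping factor yields between-individual variance σ²_A and residual
variance σ², and

R = σ²_A / (σ²_A + σ²),

classified low (R < 0.25), moderate (0.25 ≤ R ≤ 0.5; the boundary 0.5 is
labelled moderate), high (R > 0.5). Fixed-effect structures are selected
backwards from year x timing along the term hierarchy: at each step the
drop with the lowest maximum-likelihood AIC is considered and the smaller
model is kept unless the larger wins by more than 2 AIC units — the
standard parsimony reading of an AIC-difference-of-2 rule. Variance
components are always reported from REML fits of the selected structure;
AIC comparisons use ML refits, as REML likelihoods are not comparable
across fixed structures. "Adjusted" repeatability conditions on the
selected fixed effects; "non-adjusted" uses the intercept-only model. When
years shift whole birds (each bird tracked in one season), the unmodelled
year variance loads onto σ²_A, so non-adjusted R exceeds adjusted R — a
pattern the test suite reproduces by construction.

Uncertainty comes from a parametric bootstrap (default 1000 draws;
`n_boot = 200` is used in the heavier calibration runs): responses are
simulated from the fitted model, refitted, and R recomputed; the SE is the
bootstrap SD and the CI the 2.5/97.5 percentiles. The percentile bootstrap
was chosen because R is a bounded ratio whose sampling distribution is
skewed near 0 and 1, where Wald intervals misbehave. Near-zero σ²_A the
REML estimate sits on a boundary: it is exactly zero for many samples with
positive excursions otherwise, so point estimates at truth R = 0 should be
read as "small relative to σ²", not as literally zero.

## Site fidelity

The nearest-neighbour distance between consecutive trips' central phases:
for each fix of trip n+1's central phase (the focal trip), the
great-circle distance to the nearest fix of trip n's central phase, summed
and divided by the number of focal fixes. The statistic is deliberately
asymmetric (focal = later trip); it is zero iff every focal fix coincides
with some previous fix, never negative, and adding fixes to the previous
segment can only decrease it. It is computed on the 20-minute resampled
fixes — the analysis resolution — not raw fixes, so segments of different
device cadences are comparable. Pairs are formed only within a bird and
only between consecutively indexed retained trips; pairs spanning a
discarded intermediate trip are not formed by default (a stricter reading
of trip-to-trip fidelity), with `chain_retained = TRUE` to chain across
gaps instead.

## Inference on NND

All models work on log(NND). Year effects: a linear model with the first
season as reference. Year x timing: estimated marginal means per year at
the grand-mean timing with all pairwise year contrasts Tukey-adjusted
(seasons with fewer than 3 records are dropped from contrasts), plus
per-year timing slopes. Sea-ice effects: penalized cubic-regression-spline
smooths (basis dimension 10, shrinkage basis, smoothing parameter by REML)
of log NND on the pair-mean concentration or the between-trip difference,
with a bird random intercept; the fitted curve is exported on a 100-point
grid with a 95% band, on both the log and the back-transformed km scale.
With too few distinct covariate values for the basis the model falls back
to a linear term and flags it. p-values are reported to 3 decimals; no
multiplicity correction is applied beyond the Tukey family.

## The synthetic study generator

`simulate_cohort` generates the full study: per-bird trait draws, per-trip
three-phase correlated walks, injected data pathologies, nest checks,
peak-hatch dates and daily ice fields, with every generating value
recorded in a truth table. Default conditions mirror the reference
tracking study: ~130 birds in the full scenario (tests run 6–60), trip
counts drawn from the published 2–9 distribution, maximal distances
log-normal around 30 km, headings around 8° with between/within SDs of
22°/28°, log-distance SDs of 0.30/0.35 (true trait R ≈ 0.42 and 0.38 —
the moderate range reported for this system), transit at 6 km/h with 10°
per-step heading noise, foraging at 1.5 km/h, 10-minute raw cadence,
10% of recordings truncated at 80% of the trip, nest checks lagging true
returns by up to 2.5 h (the field monitoring interval), and occasional
duplicate rows and ~45 km teleport spikes to exercise the QC filters.

Walks are planar in a local km frame around the colony and mapped to
lon/lat — adequate below ~150 km, which the generator enforces (tail
patch draws beyond that range are redrawn; persistently infeasible
configurations error). The outbound leg heads to the patch at transit
speed; its duration is sized with the exact expected straightness
E[cos(heading noise)] so that the patch is reached at f1 of the trip. The
central phase is a tortuous mean-reverting walk around the patch centre
(headings biased back toward the patch beyond about a third of the
`forage_pull_km` scale, wide 60° noise) — mean reversion matters, because
a freely wandering central phase smears the inbound corner of the pooled
profile and biases the fitted f2 low. The inbound leg re-aims at the
colony each step at the speed needed to arrive on time. Trip duration is
derived from the drawn maximal distance, so in the full track generator
the duration trait inherits the distance trait's repeatability; variance-
structure calibrations therefore use `simulate_trait_data`, which draws
the trait model y = mu + season + bird + residual directly with known
σ²_A and σ².

Fidelity modes: *faithful* birds centre each trip's patch on their own
trait means (trip-to-trip spread = the within-individual SDs), *explorer*
birds draw every patch fresh from the population distribution (true R =
0). Ice fields start from a latitudinal gradient (20% at the coast to 95%
offshore) plus smooth low-frequency noise, recede by 2%/day
multiplicatively (per calendar day, noise-free fields are therefore
non-increasing), clip to [0, 100], and mask land cells within 5 km of the
colony.

What the generator does *not* emulate: tides and ice drift, polynyas,
diving behaviour, device-specific fix noise, spatial prey fields (patch
quality is implicit), and between-individual route similarity. Passing
tests show the estimators recover the generating structure of this model —
three clean phases, log-normal traits, a single patch per trip — not that
they are robust to every pathology of field data.

## Problem sizes and numerical choices

The heavier calibrations run at sizes chosen to make Monte-Carlo error
small relative to the tolerance being checked: changepoint recovery on a
20-bird x 3-trip pooled cohort (~3,000 profile points, 0.5% grid);
repeatability recovery at 100 birds x 5 trips across truth R in
{0.1, 0.25, 0.4, 0.6}, summarized as mean absolute error (the sampling SD
of a single R estimate at this size is ~0.03–0.04, so per-truth bounds
would be a seed lottery); bootstrap CI coverage over 50 replicates of 200
draws; Tukey null calibration over 100 replicates of 4 seasons x 30
records. Degenerate inputs are guarded rather than silently handled:
constant profiles, zero-variance covariates, single individuals, zero
elapsed time, closed loops (sinuosity undefined and flagged), all-masked
ice extractions.

## Known limitations

Linear lon/lat interpolation and planar walk generation are small-scale
approximations; the convex hull overstates concave prospected areas; the
speed filter's forward pass can retain a late outlier that an oracle with
lookahead would drop; NND is scale-dependent (it inherits the resampling
resolution); and AIC backward selection explores the term hierarchy
greedily rather than exhaustively — with three candidate terms the two
coincide unless ties straddle the 2-unit rule.
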