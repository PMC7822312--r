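Package: tripfidelity
Title: Foraging-Trip Consistency, Repeatability and Site Fidelity from
    Central-Place Foraging GPS Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify individual foraging consistency in
    central-place foragers (developed around Adelie penguin chick-rearing
    trips) from raw GPS deployments: track cleaning with a speed filter,
    trip splitting at a colony radius, virtual completion of truncated
    trips from nest-check returns and regular-time-step resampling;
    trip-level effort metrics (duration, cumulative and maximal distance,
    bearing); pooled two-changepoint segmentation of the normalized
    distance-time profile into outbound, central (foraging) and inbound
    phases; daily sea-ice-concentration raster handling at two grid
    resolutions with regional and along-track extraction; repeatability
    via Gaussian random-intercept mixed models (adjusted and non-adjusted
    R with parametric-bootstrap uncertainty); the nearest-neighbour-
    distance (NND) foraging-site-fidelity statistic between the central
    phases of consecutive trips; year, season-timing and sea-ice models
    of fidelity; and a seeded synthetic generator of multi-phase trips
    over receding ice fields with a full truth table for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    lme4,
    mgcv,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
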