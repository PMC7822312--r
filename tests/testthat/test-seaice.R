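make_field <- function(date = "2016-01-05", cell = 6.25, nlon = 8, nlat = 6,
                       vals = NULL, seed = 1) {
  lon <- 139 + (0:(nlon - 1)) * 0.1
  lat <- -66.8 + (0:(nlat - 1)) * 0.05
  if (is.null(vals)) {
    set.seed(seed)
    vals <- matrix(runif(nlat * nlon, 0, 100), nlat, nlon)
  }
  ice_field(date, cell, lon, lat, vals)
}

test_that("ice fields round-trip through CSV exactly and mask bad values", {
  dir <- withr::local_tempdir()
  f1 <- make_field("2016-01-05", seed = 1)
  f2 <- make_field("2016-01-06", seed = 2)
  write_icefields(list(f1, f2), dir)
  back <- load_icefields(dir)
  expect_length(back, 2)
  expect_identical(back[["2016-01-05"]]$grid, f1$grid)
  expect_identical(back[["2016-01-06"]]$grid, f2$grid)
  expect_equal(back[[1]]$cell_km, 6.25)
  # out-of-range value masked with a warning
  v <- matrix(50, 3, 3); v[2, 2] <- 105
  expect_warning(f <- ice_field("2016-01-05", 6.25, 1:3, 1:3, v), "masked")
  expect_true(is.na(f$grid[2, 2]))
  # missing requested day errors with the date listed
  expect_error(load_icefields(dir, dates = as.Date("2016-01-07")),
               "2016-01-07")
})

test_that("sample_at uses containing cells with west/south-inclusive edges", {
  f <- make_field()
  # cell centers return their own value
  expect_equal(sample_at(f, f$lon[3], f$lat[2]), f$grid[2, 3])
  # west/south edge belongs to the cell east/north of it
  expect_equal(sample_at(f, f$lon[3] - 0.05, f$lat[2]), f$grid[2, 3])
  expect_equal(sample_at(f, f$lon[3], f$lat[2] - 0.025), f$grid[2, 3])
  # outside the extent: masked with warning
  expect_warning(v <- sample_at(f, 120, -66.7), "outside")
  expect_true(is.na(v))
  # 1000 random points match a brute-force nearest-center oracle
  set.seed(33)
  px <- runif(1000, min(f$lon) - 0.04, max(f$lon) + 0.04)
  py <- runif(1000, min(f$lat) - 0.02, max(f$lat) + 0.02)
  got <- suppressWarnings(sample_at(f, px, py))
  oracle <- vapply(seq_along(px), function(i) {
    ci <- which.min(abs(f$lon - px[i])); ri <- which.min(abs(f$lat - py[i]))
    f$grid[ri, ci]
  }, 0)
  ok <- !is.na(got)
  expect_equal(got[ok], oracle[ok])
})

test_that("regridding to the fine grid preserves values blockwise", {
  const <- make_field(vals = matrix(40, 6, 8), cell = 12.5)
  fine <- regrid_to_fine(const)
  expect_true(all(fine$grid == 40))
  expect_equal(fine$cell_km, 6.25)
  expect_equal(dim(fine$grid), c(12, 16))
  # checkerboard maps to 2x2 blocks of equal value
  cb <- make_field(vals = outer(1:6, 1:8, function(i, j) ((i + j) %% 2) * 100),
                   cell = 12.5)
  fcb <- regrid_to_fine(cb)
  for (i in 1:6) for (j in 1:8) {
    expect_true(all(fcb$grid[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] ==
                      cb$grid[i, j]))
  }
  # regional mean preserved for random fields
  rf <- make_field(cell = 12.5, seed = 9)
  expect_equal(mean(regrid_to_fine(rf)$grid), mean(rf$grid), tolerance = 0.01)
  # regrid-then-sample equals sampling the coarse field directly
  set.seed(10)
  px <- runif(200, min(rf$lon), max(rf$lon))
  py <- runif(200, min(rf$lat), max(rf$lat))
  expect_equal(suppressWarnings(sample_at(regrid_to_fine(rf), px, py)),
               suppressWarnings(sample_at(rf, px, py)))
})

test_that("resolution correlation behaves at the identical/derived/null poles", {
  f <- make_field(seed = 3)
  fixes <- data.frame(timestamp = utc("2016-01-05 10:00:00"),
                      lon = runif(100, min(f$lon), max(f$lon)),
                      lat = runif(100, min(f$lat), max(f$lat)))
  same <- resolution_correlation(list(`2016-01-05` = f),
                                 list(`2016-01-05` = f), fixes)
  expect_equal(same$r, 1)
  # fine = regrid of coarse -> r = 1 exactly
  co <- make_field(cell = 12.5, seed = 4)
  fi <- regrid_to_fine(co)
  r2 <- resolution_correlation(list(`2016-01-05` = co),
                               list(`2016-01-05` = fi), fixes)
  expect_equal(r2$r, 1)
  # independent random fields at fine resolution -> near-zero correlation
  set.seed(55)
  n_side <- 100
  big <- function(s) ice_field("2016-01-05", 6.25,
                               seq(139, 140, length.out = n_side),
                               seq(-66.8, -66.2, length.out = n_side),
                               matrix(runif(n_side^2, 0, 100), n_side, n_side))
  fx <- data.frame(timestamp = utc("2016-01-05 10:00:00"),
                   lon = runif(1e4, 139, 140), lat = runif(1e4, -66.8, -66.2))
  r0 <- resolution_correlation(list(`2016-01-05` = big(1)),
                               list(`2016-01-05` = big(2)), fx)
  expect_lt(abs(r0$r), 0.1)
  expect_error(resolution_correlation(list(`2016-01-05` = f),
                                      list(`2016-01-05` = f), fixes[1:2, ]),
               "3 valid")
})

test_that("regional means agree with a point-in-polygon brute-force oracle", {
  f <- make_field(vals = matrix(30, 6, 8))
  region <- whole_study_area()
  expect_equal(mean_sic_region(list(`2016-01-05` = f), region, "2016-01-05"), 30)
  # two days at 20 and 40 average to 30
  f20 <- make_field("2016-01-05", vals = matrix(20, 6, 8))
  f40 <- make_field("2016-01-06", vals = matrix(40, 6, 8))
  expect_equal(mean_sic_region(list(`2016-01-05` = f20, `2016-01-06` = f40),
                               region, c("2016-01-05", "2016-01-06")), 30)
  # random field + triangular region vs double-loop oracle
  rf <- make_field(seed = 14)
  tri <- study_region("annual_prospected_area",
                      lon = c(139.05, 139.62, 139.3),
                      lat = c(-66.78, -66.75, -66.56))
  got <- mean_sic_region(list(`2016-01-05` = rf), tri, "2016-01-05")
  acc <- c()
  for (i in seq_along(rf$lat)) for (j in seq_along(rf$lon)) {
    if (pip_raycast(rf$lon[j], rf$lat[i], tri$lon, tri$lat))
      acc <- c(acc, rf$grid[i, j])
  }
  expect_equal(got, mean(acc))
  # zero cells inside errors
  far <- study_region("annual_prospected_area", lon = c(0, 1, 1), lat = c(0, 0, 1))
  expect_error(mean_sic_region(list(`2016-01-05` = rf), far, "2016-01-05"),
               "no grid cell")
})

test_that("prospected-area hull is correct and interior-point invariant", {
  sq_lon <- c(139, 140, 140, 139); sq_lat <- c(-66.6, -66.6, -66.2, -66.2)
  tr <- make_trip(make_fixes(0:3 * 20, sq_lon, sq_lat))
  reg <- annual_prospected_area(list(tr))
  expect_setequal(round(reg$lon, 6), sq_lon)
  # adding interior fixes leaves the hull unchanged
  tr2 <- make_trip(make_fixes(0:5 * 20, c(sq_lon, 139.5, 139.6),
                              c(sq_lat, -66.4, -66.3)), trip_index = 2L)
  reg2 <- annual_prospected_area(list(tr, tr2))
  expect_equal(sort(reg2$lon), sort(reg$lon))
  expect_equal(reg2$area_km2, reg$area_km2)
  # collinear fixes have no hull
  line <- make_trip(make_fixes(0:2 * 20, c(139, 139.5, 140),
                               c(-66.5, -66.5, -66.5)))
  expect_error(annual_prospected_area(list(line)), "hull")
})

test_that("central-phase SIC is the mean of per-fix extractions", {
  f <- make_field(vals = matrix(25, 6, 8))
  seg <- data.frame(timestamp = utc("2016-01-05 10:00:00") + 0:9 * 1200,
                    lon = rep(f$lon[4], 10), lat = rep(f$lat[3], 10))
  expect_equal(mean_sic_central_phase(seg, list(`2016-01-05` = f))$mean_sic, 25)
  # half at 10, half at 30 -> 20
  v <- matrix(10, 6, 8); v[3, ] <- 30
  f2 <- make_field(vals = v)
  seg2 <- seg; seg2$lat <- rep(c(f2$lat[1], f2$lat[3]), each = 5)
  expect_equal(mean_sic_central_phase(seg2, list(`2016-01-05` = f2))$mean_sic, 20)
  # random track over random field vs brute-force loop
  rf <- make_field(seed = 18)
  set.seed(18)
  seg3 <- data.frame(timestamp = utc("2016-01-05 10:00:00") + 0:49 * 600,
                     lon = runif(50, min(rf$lon), max(rf$lon)),
                     lat = runif(50, min(rf$lat), max(rf$lat)))
  got <- mean_sic_central_phase(seg3, list(`2016-01-05` = rf))
  oracle <- mean(vapply(1:50, function(i)
    sample_at(rf, seg3$lon[i], seg3$lat[i]), 0))
  expect_equal(got$mean_sic, oracle)
  expect_equal(got$n_used, 50)
})

test_that("trip-pair ice covariates compose from regional means", {
  mk_day <- function(d, v) make_field(d, vals = matrix(v, 6, 8))
  flds <- list(`2016-01-05` = mk_day("2016-01-05", 40),
               `2016-01-06` = mk_day("2016-01-06", 40),
               `2016-01-07` = mk_day("2016-01-07", 25),
               `2016-01-08` = mk_day("2016-01-08", 25))
  t1 <- make_outback_trip(trip_index = 1L)  # 2016-01-05
  t2 <- make_outback_trip(trip_index = 2L)
  t2$fixes$timestamp <- t2$fixes$timestamp + 2 * 86400
  t2$departure <- t2$departure + 2 * 86400
  t2$return_time <- t2$return_time + 2 * 86400
  region <- whole_study_area()
  # recession: trip n at 40, trip n+1 at 25 -> difference +15
  pr <- trip_pair_ice(t1, t2, flds, region)
  expect_equal(pr$sic_difference, 15)
  expect_equal(pr$mean_sic_pair, mean(c(40, 25)))
  # compositional check against two independent regional means
  m1 <- mean_sic_region(flds, region, "2016-01-05")
  m2 <- mean_sic_region(flds, region, "2016-01-07")
  expect_equal(pr$sic_difference, m1 - m2)
  prm <- trip_pair_ice(t1, t2, flds, region, mode = "mean_of_means")
  expect_equal(prm$mean_sic_pair, mean(c(m1, m2)))
  # constant field: difference 0
  same <- trip_pair_ice(t1, t2, flds[c(1, 2, 1, 2)] |>
                          setNames(names(flds)), region)
  expect_equal(same$sic_difference, 0)
  # non-consecutive trips rejected
  t3 <- t2; t3$trip_index <- 5L
  expect_error(trip_pair_ice(t1, t3, flds, region), "consecutive")
})
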