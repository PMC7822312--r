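# Spherical geometry primitives shared by all track computations.

# Mean Earth radius (IUGG), km. All distances in the package are great-circle
# distances on this sphere.
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised over
#' its arguments (usual recycling rules).
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1) # one degree of latitude, ~111.2 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE))
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing from one point to another
#'
#' @param lon1,lat1 Origin coordinates, decimal degrees.
#' @param lon2,lat2 Destination coordinates, decimal degrees.
#' @return Bearing in degrees: 0 = north, positive eastward, range (-180, 180].
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlon <- (lon2 - lon1) * rad
  y <- sin(dlon) * cos(lat2 * rad)
  x <- cos(lat1 * rad) * sin(lat2 * rad) -
    sin(lat1 * rad) * cos(lat2 * rad) * cos(dlon)
  b <- atan2(y, x) / rad
  ifelse(b <= -180, b + 360, b)
}

# Local azimuthal equal-area projection (Lambert), km, centred on
# (lon0, lat0). Used for hull areas; exact for area on the sphere.
.project_laea_km <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  l <- lon * rad; p <- lat * rad; l0 <- lon0 * rad; p0 <- lat0 * rad
  denom <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)
  k <- sqrt(2 / denom)
  x <- .EARTH_RADIUS_KM * k * cos(p) * sin(l - l0)
  y <- .EARTH_RADIUS_KM * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0))
  list(x = x, y = y)
}

# Shoelace polygon area; vertices in order, not necessarily closed.
.shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of a lon/lat polygon in square kilometres
#'
#' Projects the vertices with an azimuthal equal-area projection centred on
#' the polygon centroid, then applies the shoelace formula.
#'
#' @param lon,lat Polygon vertex coordinates (open or closed ring).
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), length(lon) >= 3)
  if (lon[1] == lon[length(lon)] && lat[1] == lat[length(lat)]) {
    lon <- lon[-length(lon)]; lat <- lat[-length(lat)]
  }
  pr <- .project_laea_km(lon, lat, mean(lon), mean(lat))
  .shoelace_area(pr$x, pr$y)
}

# Points-in-polygon on lon/lat vertices (mgcv's ray-crossing test).
.points_in_polygon <- function(lon, lat, poly_lon, poly_lat) {
  bnd <- cbind(poly_lon, poly_lat)
  mgcv::in.out(bnd, cbind(lon, lat))
}
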