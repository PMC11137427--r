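#' Great-circle distance in statute miles
#'
#' Haversine distance on a sphere of radius 3958.8 miles, the geodesic
#' screening metric used by the session filter (sessions separated by more
#' than 400 geodesic miles are excluded) and the baseline against which road
#' distances are compared.
#'
#' @param lat1,lon1 Numeric vectors, origin coordinates in decimal degrees.
#' @param lat2,lon2 Numeric vectors, destination coordinates in decimal
#'   degrees. Vectors are recycled to a common length.
#'
#' @return Numeric vector of great-circle distances in miles. Symmetric in
#'   its endpoints and zero for coincident points.
#' @examples
#' haversine_miles(0, 0, 1, 0) # one degree of latitude, ~69.1 miles
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_MILES * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon)) {
    stop("coordinates must be numeric", call. = FALSE)
  }
  ok <- is.na(lat) | is.na(lon) |
    (lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf(
      "invalid coordinate at position %d: lat=%s lon=%s (lat must be in [-90, 90], lon in [-180, 180])",
      bad, format(lat[bad]), format(lon[bad])
    ), call. = FALSE)
  }
  invisible(TRUE)
}

## Destination point at a given initial bearing (radians) and great-circle
## distance (miles) from a start point, on the package sphere. Used by the
## generator to place patients at an exactly known geodesic separation from
## their provider.
destination_point <- function(lat, lon, bearing, distance_miles) {
  to_rad <- pi / 180
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  delta <- distance_miles / EARTH_RADIUS_MILES
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(bearing))
  lam2 <- lam1 + atan2(
    sin(bearing) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  lam2 <- ((lam2 + pi) %% (2 * pi)) - pi
  list(lat = phi2 / to_rad, lon = lam2 / to_rad)
}
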