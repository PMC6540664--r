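#' Great-circle distance
#'
#' Spherical (haversine) great-circle distance in kilometres on a sphere of
#' radius 6,371.0 km. Symmetric, zero iff the points coincide. Vectorised.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return numeric vector of distances, km.
#' @examples
#' greatCircleKm(0, 0, 0, 90)  # quarter of the equator, ~10007.5 km
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
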