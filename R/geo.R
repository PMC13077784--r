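# Great-circle distances for choice-set construction and closest-SNF
# identification. Haversine on a sphere of mean radius 6371.0088 km; at the
# <= 25 km scales that matter here the discrepancy from an ellipsoidal
# geodesic is below 0.3% and cannot flip any documented threshold.

#' Mean Earth radius (km) used by all distance computations
#'
#' The IUGG mean radius of the reference ellipsoid, 6371.0088 km.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between coordinate pairs
#'
#' Computes the haversine great-circle distance, in kilometers, between
#' points given in decimal degrees. All four arguments are recycled to a
#' common length, so the function works elementwise on vectors.
#'
#' @param lat1,lon1 Latitude and longitude of the first point(s), decimal
#'   degrees. Latitudes must lie in \[-90, 90\], longitudes in \[-180, 180\].
#' @param lat2,lon2 Latitude and longitude of the second point(s).
#' @return Numeric vector of distances in kilometers. Symmetric,
#'   non-negative, and zero exactly when the points coincide.
#' @examples
#' distance_km(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
distance_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  phi1 <- lat1 * rad
  phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  # guard tiny negative / >1 values from floating point
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(abs(lat) > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(abs(lon) > 180)) {
    stop("longitude out of range [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

# Pairwise distance matrix between two coordinate tables (rows = points).
# Used internally for choice-set radii and nearest-k ranking.
distance_matrix_km <- function(lat1, lon1, lat2, lon2) {
  n1 <- length(lat1)
  n2 <- length(lat2)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    out[i, ] <- distance_km(lat1[i], lon1[i], lat2, lon2)
  }
  out
}
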