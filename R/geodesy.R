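#' @keywords internal
.deg2rad <- function(x) x * pi / 180

#' Mean Earth radius in statute miles
#'
#' Default sphere radius used by [haversine()] and [destination_point()].
#' @return A length-one numeric (3958.8 miles).
#' @export
earth_radius_miles <- function() 3958.8

.check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (any(lon < -180 - 1e-9 | lon > 180 + 1e-9))
    stop("longitudes must lie in [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between coordinate pairs (haversine formula)
#'
#' Distance in statute miles between points on a sphere. All arguments are
#' recycled to a common length, so the function is fully vectorised.
#'
#' @param lat1,lon1 Origin latitude/longitude in decimal degrees.
#' @param lat2,lon2 Destination latitude/longitude in decimal degrees.
#' @param radius Sphere radius in miles; defaults to [earth_radius_miles()].
#' @return Numeric vector of distances in miles (non-negative, symmetric in
#'   its two endpoints).
#' @examples
#' haversine(39.77, -86.16, 41.88, -87.63) # Indianapolis -> Chicago, ~165 mi
#' @export
haversine <- function(lat1, lon1, lat2, lon2, radius = earth_radius_miles()) {
  .check_latlon(c(lat1, lat2), c(lon1 %% 360, lon2 %% 360) - 180)
  p1 <- .deg2rad(lat1)
  p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1) # guard rounding at antipodes
  2 * radius * asin(sqrt(a))
}

#' Point reached by travelling a given distance along an initial bearing
#'
#' Direct spherical geodesy problem: starting from (`lat`, `lon`), travel
#' `distance` miles along great circle with initial bearing `bearing`.
#' Used by the synthetic cohort generator to place donor/recipient centroid
#' pairs at a prescribed great-circle separation.
#'
#' @param lat,lon Start point in decimal degrees.
#' @param bearing Initial bearing in degrees clockwise from north.
#' @param distance Distance in miles (>= 0).
#' @param radius Sphere radius in miles.
#' @return A data.frame with columns `lat` and `lon` (degrees, longitude
#'   normalised to \[-180, 180)).
#' @export
destination_point <- function(lat, lon, bearing, distance,
                              radius = earth_radius_miles()) {
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  phi1 <- .deg2rad(lat)
  lam1 <- .deg2rad(lon)
  theta <- .deg2rad(bearing)
  delta <- distance / radius
  sinphi2 <- sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta)
  phi2 <- asin(pmin(pmax(sinphi2, -1), 1))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sinphi2
  )
  lam2 <- (lam2 + pi) %% (2 * pi) - pi
  data.frame(lat = phi2 * 180 / pi, lon = lam2 * 180 / pi)
}

.gaz_lookup <- function(gazetteer, kind, keys) {
  sub <- gazetteer[gazetteer$kind == kind, , drop = FALSE]
  i <- match(keys, sub$key)
  cbind(lat = sub$lat[i], lon = sub$lon[i])
}

#' Resolve transplant records to trip distances
#'
#' Resolves each record's donor endpoint from the donor ZIP centroid and the
#' recipient endpoint from the recipient ZIP centroid, falling back to the
#' recipient city-state centroid when the recipient ZIP is missing or
#' unknown. Records with an unresolvable endpoint are dropped and counted
#' rather than aborting the run.
#'
#' @param records Data frame of transplant records (see [generate_cohort()]
#'   for the column contract: `record_id`, `organ`, `transplant_date`,
#'   `donor_zip`, `recipient_zip`, `recipient_city_state`).
#' @param gazetteer Data frame with columns `kind` (`"zip"` or
#'   `"city_state"`), `key`, `lat`, `lon`.
#' @param radius Sphere radius in miles passed to [haversine()].
#' @return A list with elements
#'   \describe{
#'     \item{trips}{data.frame: `record_id`, `organ`, `transplant_date`,
#'       `distance_miles`, `resolution_flags` (plus `region` if present in
#'       the input).}
#'     \item{n_unresolved}{count of dropped records.}
#'     \item{unresolved_ids}{their `record_id`s.}
#'   }
#' @export
resolve_trips <- function(records, gazetteer, radius = earth_radius_miles()) {
  stopifnot(is.data.frame(records), is.data.frame(gazetteer))
  don <- .gaz_lookup(gazetteer, "zip", records$donor_zip)
  rec <- .gaz_lookup(gazetteer, "zip", records$recipient_zip)
  need_fb <- is.na(rec[, "lat"])
  if (any(need_fb)) {
    fb <- .gaz_lookup(gazetteer, "city_state",
                      records$recipient_city_state[need_fb])
    rec[need_fb, ] <- fb
  }
  flags <- ifelse(need_fb, "donor_zip+city_state_fallback",
                  "donor_zip+recipient_zip")
  ok <- !is.na(don[, "lat"]) & !is.na(rec[, "lat"])
  trips <- data.frame(
    record_id = records$record_id[ok],
    organ = records$organ[ok],
    transplant_date = as.Date(records$transplant_date[ok]),
    distance_miles = haversine(don[ok, "lat"], don[ok, "lon"],
                               rec[ok, "lat"], rec[ok, "lon"], radius),
    resolution_flags = flags[ok],
    stringsAsFactors = FALSE
  )
  if (!is.null(records$region)) trips$region <- records$region[ok]
  list(
    trips = trips,
    n_unresolved = sum(!ok),
    unresolved_ids = records$record_id[!ok]
  )
}

#' Read or write a gazetteer CSV
#'
#' The gazetteer CSV has columns `kind` ("zip" or "city_state"), `key`,
#' `lat`, `lon`; keys are read as character so leading zeros survive.
#'
#' @param path File path.
#' @param gazetteer Data frame as returned by [generate_cohort()].
#' @return `read_gazetteer_csv()` returns the gazetteer data frame;
#'   `write_gazetteer_csv()` returns `path` invisibly.
#' @export
read_gazetteer_csv <- function(path) {
  utils::read.csv(path, colClasses = c(
    kind = "character", key = "character",
    lat = "numeric", lon = "numeric"
  ))
}

#' @rdname read_gazetteer_csv
#' @export
write_gazetteer_csv <- function(gazetteer, path) {
  utils::write.csv(gazetteer, path, row.names = FALSE)
  invisible(path)
}
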