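# Transect geometry: great-circle distances and min-max scaling of the
# sampling transect onto [0, 1], the x-axis of all cline fits.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between two points (Haversine formula)
#'
#' Uses the mean Earth radius R = 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres (vectorized).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90 | abs(lat2) > 90)) {
    stop_validation("latitude out of [-90, 90]")
  }
  if (any(abs(lon1) > 180 | abs(lon2) > 180)) {
    stop_validation("longitude out of [-180, 180]")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Scale samples onto a 0-1 transect
#'
#' Computes the Haversine distance of every sample from an anchor sample
#' and min-max normalizes to \[0, 1\], independently within each contact
#' zone. The anchor operationalizes "closest to the coast" as the
#' westernmost sample (minimum longitude) unless an explicit id is given.
#'
#' @param samples Sample table (see [read_sample_table()]).
#' @param anchor_rule `"westernmost"`, or a named list/character vector
#'   mapping contact zone to an explicit anchor `sample_id`.
#' @return A `data.frame` with `sample_id`, `contact_zone`, `distance_km`,
#'   `distance_scaled`.
#' @export
scale_transect <- function(samples, anchor_rule = "westernmost") {
  out <- lapply(split(samples, samples$contact_zone), function(z) {
    if (nrow(z) < 2) {
      stop_validation("contact zone '%s' has fewer than 2 samples",
                      z$contact_zone[1])
    }
    anchor_idx <- if (identical(anchor_rule, "westernmost")) {
      which.min(z$lon)
    } else {
      id <- anchor_rule[[z$contact_zone[1]]] %||% anchor_rule[[1]]
      idx <- match(id, z$sample_id)
      if (is.na(idx)) {
        stop_validation("anchor sample '%s' not found in zone '%s'",
                        id, z$contact_zone[1])
      }
      idx
    }
    d <- haversine_km(z$lat[anchor_idx], z$lon[anchor_idx], z$lat, z$lon)
    if (max(d) == 0) {
      stop_validation("degenerate transect in zone '%s': all samples co-located",
                      z$contact_zone[1])
    }
    data.frame(sample_id = z$sample_id, contact_zone = z$contact_zone,
               distance_km = d, distance_scaled = d / max(d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[match(samples$sample_id, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
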