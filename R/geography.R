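#' Generate a deterministic suburb/postcode/region lookup
#'
#' Builds a flat geography table for the synthetic study area: regions
#' (statistical areas) containing suburbs whose midpoints sit on a planar
#' grid, each suburb carrying one 4-digit postcode. Consecutive suburb
#' pairs share a postcode, so every postcode maps to exactly one region
#' while some postcodes cover two suburbs (which is what makes modal-suburb
#' imputation meaningful). Urban regions carry larger populations. The
#' table is fully deterministic: no random draws are used.
#'
#' @param n_regions number of regions.
#' @param suburbs_per_region suburbs in each region (recycled).
#' @param n_urban how many regions (the first ones) are urban.
#' @param base_lat,base_lon south-west corner of the study area in WGS84
#'   degrees.
#' @param grid_step grid spacing between suburb midpoints, in degrees
#'   (0.02 degrees is roughly 2 km at these latitudes).
#' @return tibble with columns `suburb`, `postcode`, `region`,
#'   `region_population`, `urban`, `latitude`, `longitude`.
#' @export
#' @examples
#' generate_geography(n_regions = 2, suburbs_per_region = 4)
generate_geography <- function(n_regions = 6,
                               suburbs_per_region = 8,
                               n_urban = 2,
                               base_lat = -34.0,
                               base_lon = 150.5,
                               grid_step = 0.02) {
  assert_that(n_regions >= 1 && n_urban <= n_regions, "invalid region counts")
  suburbs_per_region <- rep_len(suburbs_per_region, n_regions)
  first <- c(
    "spring", "oak", "fern", "river", "stone", "hill", "marsh", "wattle",
    "clear", "iron", "ash", "birch", "cedar", "elm", "glen", "haze",
    "lake", "moor", "north", "sand"
  )
  second <- c("vale", "wood", "field", "ridge", "brook", "haven", "dale", "port")
  suburb_name <- function(k) {
    paste0(first[(k - 1) %% length(first) + 1], second[((k - 1) %/% length(first)) %% length(second) + 1])
  }
  k0 <- 0L
  out <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    n_sub <- suburbs_per_region[r]
    side <- ceiling(sqrt(n_sub))
    idx <- seq_len(n_sub)
    # each region occupies its own longitude band so regions do not overlap
    lon0 <- base_lon + (r - 1) * (side + 3) * grid_step
    urban <- r <= n_urban
    out[[r]] <- tibble(
      suburb = map_chr(k0 + idx, suburb_name),
      postcode = sprintf("2%03d", (r - 1) * 100 + (idx - 1) %/% 2),
      region = sprintf("R%02d", r),
      region_population = if (urban) 420000L + r * 1000L else 140000L + r * 1000L,
      urban = urban,
      latitude = base_lat + ((idx - 1) %/% side) * grid_step,
      longitude = lon0 + ((idx - 1) %% side) * grid_step
    )
    k0 <- k0 + n_sub
  }
  geo <- bind_rows(out)
  assert_that(!anyDuplicated(geo[c("suburb", "postcode")]), "duplicate (suburb, postcode) pair")
  geo
}

#' Equirectangular distance in kilometres
#'
#' Planar approximation to great-circle distance,
#' `d = R * sqrt(dphi^2 + (cos(phi_m) * dlambda)^2)` with angles in radians
#' and `R = 6371` km. At suburb scales (tens of km) the error against the
#' haversine distance is negligible, and the formula keeps delivery-coverage
#' checks trivially reproducible by hand.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in WGS84 degrees (vectorised).
#' @return distance in km.
#' @export
equirect_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  phim <- (lat1 + lat2) / 2 * rad
  6371 * sqrt(dphi^2 + (cos(phim) * dlam)^2)
}
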