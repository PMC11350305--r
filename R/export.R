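#' CSV and JSON exports
#'
#' All tabular artefacts are written as UTF-8, comma-delimited CSV with a
#' header row; list columns (descriptors, member ids) are packed with a
#' `|` separator and unpacked symmetrically on read, so every file written
#' by one stage is re-readable by the next.
#'
#' @name io_export
NULL

LIST_COLS <- c("category_descriptors", "descriptors", "ids")

#' @rdname io_export
#' @param df tibble to write; list columns are packed.
#' @param path file path.
#' @export
write_outlets_csv <- function(df, path) {
  for (col in intersect(LIST_COLS, names(df))) {
    df[[col]] <- pack_descriptors(df[[col]])
  }
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' @rdname io_export
#' @export
read_outlets_csv <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = ""
  )
  for (col in intersect(c("latitude", "longitude", "density"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("n" %in% names(df)) df$n <- as.integer(df$n)
  for (col in intersect(LIST_COLS, names(df))) {
    df[[col]] <- unpack_descriptors(df[[col]])
  }
  for (col in intersect(
    c("imputed_suburb", "imputed_postcode", "imputed_street_number",
      "state_reject", "name_empty", "tie_broken", "urban"),
    names(df)
  )) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Export per-postcode environment features as GeoJSON
#'
#' Writes a GeoJSON FeatureCollection of Point features (WGS84, lon-lat
#' ordering), one per postcode, positioned at the mean midpoint of the
#' postcode's suburbs, with the per-scope outlet counts, the
#' percent-change statistic, and the relative density as properties.
#'
#' @param views an `environment_views` tibble.
#' @param geography the geography lookup.
#' @param path output path.
#' @export
export_postcode_geojson <- function(views, geography, path) {
  pts <- geography |>
    group_by(.data$postcode) |>
    summarise(
      lat = mean(.data$latitude), lon = mean(.data$longitude),
      region = first(.data$region), .groups = "drop"
    )
  counts <- views |>
    filter(.data$unit_level == "postcode") |>
    select(postcode = "unit", "scope", "n") |>
    tidyr::pivot_wider(
      names_from = "scope", values_from = "n",
      names_prefix = "n_", values_fill = 0L
    )
  dens <- density_by_postcode(views) |> select("postcode", "density")
  feat_tbl <- pts |>
    inner_join(counts, by = "postcode") |>
    left_join(dens, by = "postcode") |>
    mutate(pct_change = pct_change(.data$n_local, .data$n_hybrid))
  features <- pmap(feat_tbl, function(postcode, lat, lon, region, n_local,
                                      n_online, n_hybrid, density, pct_change, ...) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(lon, lat)),
      properties = list(
        postcode = postcode, region = region,
        n_local = n_local, n_online = n_online, n_hybrid = n_hybrid,
        pct_change = pct_change, density = density
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname io_export
#' @param freqs a [cuisine_frequencies()] tibble (word-cloud payload).
#' @export
write_wordcloud_json <- function(freqs, path) {
  jsonlite::write_json(freqs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
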