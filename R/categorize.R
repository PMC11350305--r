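#' Detect franchise brands
#'
#' A franchise is a brand (identical normalised name) with strictly more
#' than `threshold` distinct physical locations across the combined
#' datasets — a deliberately generous bar compared with menu-labelling
#' legislation (which uses 20 state-wide / 50 national locations), so that
#' incomplete listings do not demote a true franchise. Distinct locations
#' are distinct (street number, street name, suburb) triples; matched
#' online/local pairs are counted once by dropping the local twin of every
#' match before counting.
#'
#' @param outlets combined normalised outlets (online deduplicated + local
#'   filtered).
#' @param matches matches tibble from [run_cascade()] (or `NULL`).
#' @param threshold strict lower bound: brands qualify with
#'   `> threshold` locations (default 10, so 11 locations qualify and 10
#'   does not).
#' @return tibble `brand`, `n_locations`, sorted by brand.
#' @export
detect_franchises <- function(outlets, matches = NULL, threshold = 10L) {
  if (!is.null(matches) && nrow(matches) > 0) {
    outlets <- outlets |>
      filter(!(.data$source == "local" & .data$source_id %in% matches$local_id))
  }
  outlets |>
    filter(nzchar(.data$name_norm)) |>
    distinct(.data$name_norm, .data$street_number, .data$street_name, .data$suburb_norm) |>
    count(.data$name_norm, name = "n_locations") |>
    filter(.data$n_locations > threshold) |>
    rename(brand = "name_norm") |>
    arrange(.data$brand)
}

#' Score an outlet's descriptors against the category lexicon
#'
#' The cumulative score of a category is the sum, over the outlet's
#' descriptors, of that descriptor's weight for the category.
#' Multi-category descriptors contribute their weight to each mapped
#' category; descriptors absent from the lexicon contribute nothing.
#'
#' @param descriptors character vector of descriptors for one outlet.
#' @param lexicon a [default_lexicon()]-shaped tibble.
#' @return tibble `category`, `score` covering every category in
#'   [main_categories()] plus the auxiliary alcohol retailer (zeros kept).
#' @export
#' @examples
#' score_categories(c("comfort food", "burger", "salad"))
score_categories <- function(descriptors, lexicon = default_lexicon()) {
  cats <- main_categories(auxiliary = TRUE)
  d <- str_squish(str_to_lower(descriptors))
  hits <- lexicon |>
    filter(.data$descriptor %in% d, !is.na(.data$category)) |>
    inner_join(tibble(descriptor = d), by = "descriptor", relationship = "many-to-many") |>
    count(.data$category, wt = .data$weight, name = "score")
  tibble(category = cats) |>
    left_join(hits, by = "category") |>
    mutate(score = as.integer(coalesce(.data$score, 0L)))
}

#' Assign the main category from cumulative scores
#'
#' The category with the unique maximal cumulative score wins. When maxima
#' tie, the tied category that appears least frequently in the global
#' category frequency table wins (prioritising rarer categories counters
#' the over-representation of the dominant ones); a residual tie falls
#' back to the fixed [main_categories()] order. All-zero scores yield
#' `NA`.
#'
#' @param scores tibble from [score_categories()].
#' @param frequencies named integer vector of global category frequencies
#'   (categories absent from the table count 0).
#' @return list with `main_category` (character or `NA`) and `tie_broken`.
#' @export
assign_main_category <- function(scores, frequencies = integer()) {
  mx <- max(scores$score)
  if (mx == 0) {
    return(list(main_category = NA_character_, tie_broken = FALSE))
  }
  tied <- scores$category[scores$score == mx]
  if (length(tied) == 1) {
    return(list(main_category = tied, tie_broken = FALSE))
  }
  freq <- frequencies[tied]
  freq[is.na(freq)] <- 0L
  ord <- order(freq, match(tied, main_categories(auxiliary = TRUE)))
  list(main_category = tied[ord[1]], tie_broken = TRUE)
}

# Vectorised scoring over an outlet table -> long scores keyed by row.
score_outlet_table <- function(outlets, lexicon) {
  if (nrow(outlets) == 0) {
    return(tibble(.row = integer(), category = character(), score = integer()))
  }
  outlets |>
    mutate(.row = row_number()) |>
    select(".row", "descriptors") |>
    unnest_longer("descriptors", values_to = "descriptor") |>
    mutate(descriptor = str_squish(str_to_lower(.data$descriptor))) |>
    inner_join(
      lexicon |> filter(!is.na(.data$category)),
      by = "descriptor", relationship = "many-to-many"
    ) |>
    count(.data$.row, .data$category, wt = .data$weight, name = "score")
}

#' Score and categorise a table of outlets
#'
#' Two-pass assignment: global category frequencies are computed from the
#' outlets with a unique maximal score (a provisional pass), frozen, and
#' then used to break ties in the final pass. A pre-computed frequency
#' table may be supplied instead (e.g. the combined-dataset table when
#' categorising one source at a time).
#'
#' @param outlets normalised outlet tibble with a `descriptors` list
#'   column.
#' @param lexicon descriptor lexicon.
#' @param frequencies optional frozen frequency table (named vector).
#' @return tibble `source`, `source_id`, `main_category`, `tie_broken`,
#'   `assignment_source = "scored"`, with the frequency table used as the
#'   `"category_frequencies"` attribute.
#' @export
categorize_outlets <- function(outlets, lexicon = default_lexicon(), frequencies = NULL) {
  long <- score_outlet_table(outlets, lexicon)
  per_row <- long |>
    group_by(.data$.row) |>
    summarise(
      mx = max(.data$score),
      n_at_max = sum(.data$score == max(.data$score)),
      .groups = "drop"
    )
  if (is.null(frequencies)) {
    uniq <- long |>
      inner_join(per_row |> filter(.data$n_at_max == 1), by = ".row") |>
      filter(.data$score == .data$mx)
    frequencies <- table(uniq$category)
    frequencies <- setNames(as.integer(frequencies), names(frequencies))
  }
  cat_order <- main_categories(auxiliary = TRUE)
  freq_of <- function(cat) {
    f <- frequencies[cat]
    f[is.na(f)] <- 0L
    as.integer(f)
  }
  winners <- long |>
    group_by(.data$.row) |>
    filter(.data$score == max(.data$score)) |>
    arrange(freq_of(.data$category), match(.data$category, cat_order), .by_group = TRUE) |>
    summarise(
      main_category = first(.data$category),
      tie_broken = n() > 1,
      .groups = "drop"
    )
  out <- outlets |>
    mutate(.row = row_number()) |>
    select("source", "source_id", ".row") |>
    left_join(winners, by = ".row") |>
    mutate(
      tie_broken = coalesce(.data$tie_broken, FALSE),
      assignment_source = "scored"
    ) |>
    select(-".row")
  attr(out, "category_frequencies") <- frequencies
  out
}

#' Subtype franchise brands
#'
#' Looks each brand up in the subtype lexicon; brands absent from it are
#' subtyped from their pooled descriptors by keyword precedence — dessert
#' (sweets, cakes, ice cream, sugar-sweetened drinks), then bakery, then
#' juice, then healthy (salads, sushi, sandwiches) — defaulting to
#' unhealthy (the fast-food profile of burgers, pizza, fried chicken).
#'
#' @param brands character vector of franchise brand names (normalised).
#' @param subtype_lexicon tibble `brand`, `subtype`.
#' @param brand_descriptors named list: pooled descriptors per brand (used
#'   for brands missing from the lexicon).
#' @return character vector of subtypes, one per brand.
#' @export
subtype_franchise <- function(brands, subtype_lexicon = default_subtype_lexicon(),
                              brand_descriptors = list()) {
  kw <- subtype_keywords()
  map_chr(brands, function(b) {
    hit <- subtype_lexicon$subtype[subtype_lexicon$brand == b]
    if (length(hit) > 0 && !is.na(hit[1])) {
      return(hit[1])
    }
    d <- str_to_lower(unlist(brand_descriptors[[b]] %||% character()))
    for (s in names(kw)) {
      if (any(d %in% kw[[s]])) {
        return(s)
      }
    }
    "unhealthy"
  })
}

#' Transfer main categories across matched outlets
#'
#' Every matched local outlet takes its online twin's main category
#' (`assignment_source = "transferred"`); unmatched local outlets keep
#' their own scored assignment.
#'
#' @param assignments_local scored local assignments.
#' @param assignments_online online assignments.
#' @param matches matches tibble (`online_id`, `local_id`).
#' @return updated local assignments.
#' @export
transfer_categories <- function(assignments_local, assignments_online, matches) {
  twin <- matches |>
    select(source_id = "local_id", online_id = "online_id") |>
    left_join(
      assignments_online |>
        select(online_id = "source_id", twin_category = "main_category"),
      by = "online_id"
    )
  assignments_local |>
    left_join(twin |> select("source_id", "twin_category"), by = "source_id") |>
    mutate(
      main_category = coalesce(.data$twin_category, .data$main_category),
      assignment_source = ifelse(!is.na(.data$twin_category), "transferred", .data$assignment_source),
      tie_broken = ifelse(!is.na(.data$twin_category), FALSE, .data$tie_broken)
    ) |>
    select(-"twin_category")
}

#' Full categorisation of both sources
#'
#' Orchestrates the categorisation flow: franchise detection over the
#' combined datasets; franchise outlets labelled `takeaway_franchise` with
#' a subtype; online non-franchise outlets scored against the lexicon;
#' matched local outlets receiving their online twin's category; remaining
#' local outlets scored against the local lexicon. Tie-breaking
#' frequencies are computed once from the combined non-franchise outlets
#' and frozen.
#'
#' @param local,online normalised outlet tibbles (local filtered, online
#'   deduplicated).
#' @param matches matches tibble from [run_cascade()].
#' @param lexicon descriptor lexicon for the online source.
#' @param lexicon_local descriptor lexicon for the local source (defaults
#'   to the same table).
#' @param subtype_lexicon franchise subtype lexicon.
#' @param franchise_threshold strict franchise location bound.
#' @return tibble `source`, `source_id`, `main_category`, `subtype`,
#'   `assignment_source`, `tie_broken`; the franchise registry is attached
#'   as attribute `"franchise_registry"`.
#' @export
assign_categories <- function(local, online, matches,
                              lexicon = default_lexicon(),
                              lexicon_local = lexicon,
                              subtype_lexicon = default_subtype_lexicon(),
                              franchise_threshold = 10L) {
  combined <- bind_rows(online, local)
  registry <- detect_franchises(combined, matches, franchise_threshold)
  is_fr_online <- online$name_norm %in% registry$brand
  is_fr_local <- local$name_norm %in% registry$brand

  brand_desc <- combined |>
    filter(.data$name_norm %in% registry$brand) |>
    group_by(.data$name_norm) |>
    summarise(d = list(unique(unlist(.data$descriptors))), .groups = "drop")
  brand_descriptors <- setNames(brand_desc$d, brand_desc$name_norm)
  registry$subtype <- subtype_franchise(registry$brand, subtype_lexicon, brand_descriptors)
  subtype_of <- setNames(registry$subtype, registry$brand)

  nonfr <- bind_rows(online[!is_fr_online, ], local[!is_fr_local, ])
  freq <- attr(categorize_outlets(nonfr, lexicon), "category_frequencies")

  franchise_assign <- function(df) {
    tibble(
      source = df$source, source_id = df$source_id,
      main_category = "takeaway_franchise",
      subtype = unname(subtype_of[df$name_norm]),
      assignment_source = "franchise", tie_broken = FALSE
    )
  }
  on_fr <- franchise_assign(online[is_fr_online, ])
  lo_fr <- franchise_assign(local[is_fr_local, ])

  on_scored <- categorize_outlets(online[!is_fr_online, ], lexicon, freq) |>
    mutate(subtype = NA_character_)
  lo_scored <- categorize_outlets(local[!is_fr_local, ], lexicon_local, freq) |>
    mutate(subtype = NA_character_)
  lo_scored <- transfer_categories(lo_scored, on_scored, matches)

  out <- bind_rows(on_fr, on_scored, lo_fr, lo_scored) |>
    select(
      "source", "source_id", "main_category", "subtype",
      "assignment_source", "tie_broken"
    )
  attr(out, "franchise_registry") <- registry
  out
}
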