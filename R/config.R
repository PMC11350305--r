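#' Normalisation configuration
#'
#' Token lists driving listing-text normalisation: the target state (rows
#' from other states are rejected), the city and state tokens stripped from
#' outlet names, the shopping-centre/building and petrol-station name lists
#' whose occurrences are removed from names and addresses, and the street
#' type vocabulary with its abbreviation map ("st" -> "street"). The centre
#' list stands in for a manually curated inventory of food courts, centres,
#' and multilevel buildings; extend it for real sources.
#'
#' @param target_state state whose rows are kept (compared case-insensitively
#'   against both the abbreviation and the long name).
#' @param state_tokens spelled-out state tokens removed from names/addresses.
#' @param city_tokens city tokens removed from names/addresses.
#' @param centre_list shopping centre / building / food court names.
#' @param petrol_list petrol station brand names.
#' @param street_types closed vocabulary of canonical street types.
#' @param street_abbrev named character vector mapping abbreviations to
#'   canonical street types.
#' @param nonfood non-food category tags used by [filter_local()].
#' @return a list of class `norm_config`.
#' @export
norm_config <- function(target_state = "nsw",
                        state_tokens = c("nsw", "new south wales"),
                        city_tokens = "sydney",
                        centre_list = c(
                          "westfield", "central park", "spice alley",
                          "market plaza", "harbour arcade", "stockland mall"
                        ),
                        petrol_list = c("shell", "bp", "ampol", "caltex"),
                        street_types = c(
                          "street", "road", "avenue", "lane", "drive",
                          "parade", "place", "highway", "crescent", "boulevard"
                        ),
                        street_abbrev = c(
                          st = "street", rd = "road", ave = "avenue",
                          av = "avenue", ln = "lane", dr = "drive",
                          pde = "parade", pl = "place", hwy = "highway",
                          cres = "crescent", blvd = "boulevard"
                        ),
                        nonfood = nonfood_tags()) {
  structure(
    list(
      target_state = target_state, state_tokens = state_tokens,
      city_tokens = city_tokens, centre_list = centre_list,
      petrol_list = petrol_list, street_types = street_types,
      street_abbrev = street_abbrev, nonfood = nonfood
    ),
    class = "norm_config"
  )
}

#' Simulation configuration for the outlet universe
#'
#' Study conditions for the synthetic food-outlet universe. Outlets are
#' allocated to regions in proportion to region population (largest
#' remainder) unless explicit per-region counts are supplied. Franchise
#' brands are placed with fixed per-brand location counts; independent
#' outlets draw a category from `category_mix` and carry descriptors
#' diagnostic of it. Delivery-platform participation is Bernoulli with a
#' higher probability in urban than rural regions, reflecting the urban
#' skew of delivery platforms; participating outlets deliver to every
#' suburb within their delivery radius (platforms advertise delivery to
#' suburbs several kilometres out, so radii default to 1-6 km around the
#' 3 km scale typical of delivery trips).
#'
#' @param n_outlets total number of outlets when `outlets_per_region` is
#'   `NULL`.
#' @param outlets_per_region optional named integer vector of counts per
#'   region id.
#' @param franchise_brands tibble with columns `brand`, `n_locations` (and
#'   optionally `subtype`).
#' @param category_mix named probability vector over non-franchise main
#'   categories (auxiliary alcohol retailer included); normalised to sum 1.
#' @param p_delivery_urban,p_delivery_rural platform participation
#'   probabilities by region urbanicity; urban must exceed rural.
#' @param delivery_radius_range delivery radius range in km, sampled
#'   uniformly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_outlets = 600L,
                       outlets_per_region = NULL,
                       franchise_brands = default_franchise_brands(),
                       category_mix = default_category_mix(),
                       p_delivery_urban = 0.6,
                       p_delivery_rural = 0.1,
                       delivery_radius_range = c(1, 6)) {
  assert_that(n_outlets >= 0 && all(category_mix >= 0), "counts and probabilities must be non-negative")
  assert_that(
    is.null(outlets_per_region) || all(outlets_per_region >= 0),
    "negative per-region outlet counts are not allowed"
  )
  assert_that(
    all(franchise_brands$n_locations >= 0),
    "negative franchise location counts are not allowed"
  )
  assert_that(
    p_delivery_urban > p_delivery_rural,
    "urban delivery participation must exceed rural participation"
  )
  structure(
    list(
      n_outlets = as.integer(n_outlets),
      outlets_per_region = outlets_per_region,
      franchise_brands = as_tibble(franchise_brands),
      category_mix = category_mix / sum(category_mix),
      p_delivery_urban = p_delivery_urban,
      p_delivery_rural = p_delivery_rural,
      delivery_radius_range = delivery_radius_range
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_franchise_brands <- function() {
  tribble(
    ~brand, ~n_locations, ~subtype,
    "burger barn", 25L, "unhealthy",
    "chicken champion", 18L, "unhealthy",
    "pizza planet", 15L, "unhealthy",
    "gelato galaxy", 13L, "dessert",
    "crust and crumb", 12L, "bakery",
    "juice junction", 11L, "juice",
    "green bowl", 11L, "healthy",
    "noodle nest", 6L, NA_character_
  )
}

#' @rdname sim_config
#' @export
default_category_mix <- function() {
  # Category proportions of a directory-scraped state-wide food environment:
  # independent restaurants/cafes dominate at roughly half, independent
  # takeaways next, the retail categories in single digits.
  mix <- c(
    independent_restaurant_cafe = 0.472,
    independent_takeaway = 0.109,
    supermarket_grocer = 0.066,
    alcohol_retailer = 0.061,
    convenience_petrol = 0.057,
    fresh_produce = 0.057,
    sweets_extra = 0.044,
    bakery = 0.032,
    sandwich_salad = 0.014
  )
  mix / sum(mix)
}

#' Noise configuration for the rendered listing views
#'
#' Rates of the listing-noise modes observed in scraped business
#' directories: missing suburbs/postcodes/street numbers, shopping-centre
#' or building prefixes on addresses, name "decoration" with suburb, city,
#' state or petrol-station tokens, case shuffling, stray punctuation, and
#' (for the local directory view) contamination with non-food businesses
#' and permanently closed listings. All noise is applied per row from a
#' seed-keyed substream so insertion order never changes outcomes.
#'
#' `n_delivery_suburbs_mean` is informational: delivery-suburb rows are
#' derived deterministically from each outlet's delivery radius rather than
#' sampled, so oracle checks on row counts are exact; the field records the
#' expected per-outlet row count the default radii imply.
#'
#' @param seed integer seed for the noise substreams.
#' @param p_missing_suburb,p_missing_postcode,p_missing_both,p_missing_street_number
#'   missingness probabilities.
#' @param p_centre_prefix probability an address gains a centre prefix.
#' @param p_name_decoration probability a name gains location tokens.
#' @param p_case_shuffle,p_punctuation formatting-noise probabilities.
#' @param p_nonfood_rows,p_closed_rows contamination rates for the local view.
#' @param n_delivery_suburbs_mean informational expected delivery-suburb
#'   rows per online outlet.
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(seed = 1L,
                         p_missing_suburb = 0.05,
                         p_missing_postcode = 0.03,
                         p_missing_both = 0.01,
                         p_missing_street_number = 0.05,
                         p_centre_prefix = 0.10,
                         p_name_decoration = 0.10,
                         p_case_shuffle = 0.50,
                         p_punctuation = 0.30,
                         p_nonfood_rows = 0.08,
                         p_closed_rows = 0.05,
                         n_delivery_suburbs_mean = 4) {
  cfg <- list(
    seed = as.integer(seed),
    p_missing_suburb = p_missing_suburb,
    p_missing_postcode = p_missing_postcode,
    p_missing_both = p_missing_both,
    p_missing_street_number = p_missing_street_number,
    p_centre_prefix = p_centre_prefix,
    p_name_decoration = p_name_decoration,
    p_case_shuffle = p_case_shuffle,
    p_punctuation = p_punctuation,
    p_nonfood_rows = p_nonfood_rows,
    p_closed_rows = p_closed_rows,
    n_delivery_suburbs_mean = n_delivery_suburbs_mean
  )
  probs <- unlist(cfg[startsWith(names(cfg), "p_")])
  assert_that(all(probs >= 0 & probs <= 1), "all noise probabilities must lie in [0, 1]")
  structure(cfg, class = "noise_config")
}

#' Zero-noise configuration
#' @param seed integer seed (kept for schema compatibility; no draws occur).
#' @return a `noise_config` with every rate 0.
#' @export
zero_noise <- function(seed = 1L) {
  noise_config(
    seed = seed,
    p_missing_suburb = 0, p_missing_postcode = 0, p_missing_both = 0,
    p_missing_street_number = 0, p_centre_prefix = 0, p_name_decoration = 0,
    p_case_shuffle = 0, p_punctuation = 0, p_nonfood_rows = 0,
    p_closed_rows = 0
  )
}

#' Similarity thresholds for the matching cascade
#'
#' Two similarity scales are used side by side: a Jaro similarity on
#' \[0, 1\] and a normalised Levenshtein ratio on \[0, 100\]. The relaxed
#' cascade steps that drop name equality (steps 10-11) accept pairs whose
#' name ratio reaches `step10_11_name_min`; the loosest steps and the final
#' similarity pass require name AND address similarity above both `jaro_min`
#' and `levenshtein_ratio_min` on their respective scales.
#'
#' @param jaro_min minimum Jaro similarity, on \[0, 1\].
#' @param levenshtein_ratio_min minimum Levenshtein ratio, on \[0, 100\].
#' @param step10_11_name_min name-ratio threshold for cascade steps 10-11,
#'   on \[0, 100\].
#' @return a list of class `similarity_thresholds`.
#' @export
similarity_thresholds <- function(jaro_min = 0.90,
                                  levenshtein_ratio_min = 90,
                                  step10_11_name_min = 83) {
  assert_that(jaro_min >= 0 && jaro_min <= 1, "jaro_min must lie in [0, 1]")
  assert_that(
    levenshtein_ratio_min >= 0 && levenshtein_ratio_min <= 100 &&
      step10_11_name_min >= 0 && step10_11_name_min <= 100,
    "ratio thresholds must lie in [0, 100]"
  )
  structure(
    list(
      jaro_min = jaro_min,
      levenshtein_ratio_min = levenshtein_ratio_min,
      step10_11_name_min = step10_11_name_min
    ),
    class = "similarity_thresholds"
  )
}

#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters plus the global seed. Round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()]; unknown keys in a config file are rejected.
#'
#' @param seed global integer seed.
#' @param geography list of arguments for [generate_geography()].
#' @param sim a [sim_config()].
#' @param noise a [noise_config()].
#' @param thresholds a [similarity_thresholds()].
#' @param franchise_threshold strict lower bound on distinct locations for
#'   franchise status (a brand qualifies with more than this many).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            geography = list(),
                            sim = sim_config(),
                            noise = noise_config(seed = seed),
                            thresholds = similarity_thresholds(),
                            franchise_threshold = 10L) {
  structure(
    list(
      seed = as.integer(seed), geography = geography, sim = sim,
      noise = noise, thresholds = thresholds,
      franchise_threshold = as.integer(franchise_threshold)
    ),
    class = "pipeline_config"
  )
}

pipeline_config_keys <- function() {
  c("seed", "geography", "sim", "noise", "thresholds", "franchise_threshold")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path for the YAML representation.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$franchise_brands <- as.list(x$sim$franchise_brands)
  x$sim$category_mix <- as.list(x$sim$category_mix)
  if (!is.null(x$sim$outlets_per_region)) {
    x$sim$outlets_per_region <- as.list(x$sim$outlets_per_region)
  }
  x$noise <- unclass(x$noise)
  x$thresholds <- unclass(x$thresholds)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), pipeline_config_keys())
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config keys: ", paste(unknown, collapse = ", ")))
  }
  sim <- x$sim
  sim$franchise_brands <- as_tibble(sim$franchise_brands)
  for (field in c("category_mix", "delivery_radius_range", "outlets_per_region")) {
    if (!is.null(sim[[field]])) sim[[field]] <- unlist(sim[[field]])
  }
  pipeline_config(
    seed = x$seed %||% 1L,
    geography = x$geography %||% list(),
    sim = do.call(sim_config, sim),
    noise = do.call(noise_config, x$noise %||% list()),
    thresholds = do.call(similarity_thresholds, x$thresholds %||% list()),
    franchise_threshold = x$franchise_threshold %||% 10L
  )
}
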