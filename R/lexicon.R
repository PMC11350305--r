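#' The nine main outlet categories
#'
#' Healthfulness-oriented outlet taxonomy used throughout: takeaway
#' franchises, independent takeaways, independent restaurants or cafes,
#' supermarkets or grocers, fresh produce, sandwich or salad shops,
#' sweets/extra foods, bakeries, and convenience stores or petrol stations.
#' `alcohol_retailer` is carried as an auxiliary category (it can receive
#' descriptor scores and appears in composition tables but is not one of the
#' nine). The vector order is also the fixed fallback order when score
#' tie-breaking by rarity is itself tied.
#'
#' @param auxiliary include the auxiliary `alcohol_retailer` category.
#' @return character vector of category identifiers.
#' @export
main_categories <- function(auxiliary = FALSE) {
  out <- c(
    "takeaway_franchise", "independent_takeaway", "independent_restaurant_cafe",
    "supermarket_grocer", "fresh_produce", "sandwich_salad",
    "sweets_extra", "bakery", "convenience_petrol"
  )
  if (auxiliary) out <- c(out, "alcohol_retailer")
  out
}

#' Franchise subtypes
#' @return character vector of the five franchise subtypes.
#' @export
franchise_subtypes <- function() {
  c("dessert", "bakery", "juice", "healthy", "unhealthy")
}

#' Default descriptor-to-category scoring lexicon
#'
#' Maps free-text category descriptors (cuisine tags) to main categories
#' with integer weights. Every descriptor carries a base weight of 2;
#' prominent generic tags are up-weighted to 4 ("fast food") and niche tags
#' down-weighted to 1 ("japanese set item"). Some descriptors map to more
#' than one category and contribute their weight to each: "grocer" scores
#' both supermarkets and fresh produce, "hotel" scores alcohol retailer and
#' independent restaurant or cafe, and "restaurant" scores independent
#' restaurant or cafe and independent takeaway. Descriptors mapped to
#' category `NA` are known non-food tags; descriptors absent from the
#' lexicon contribute nothing.
#'
#' The table is deliberately editable: real deployments extend it with the
#' full descriptor inventory of their sources via `rbind()` or a config
#' file.
#'
#' @param extra optional tibble with columns `descriptor`, `category`,
#'   `weight` appended to the defaults (later rows win on duplicates).
#' @return tibble with columns `descriptor`, `category`, `weight`.
#' @export
#' @examples
#' default_lexicon()
default_lexicon <- function(extra = NULL) {
  lex <- tribble(
    ~descriptor, ~category, ~weight,
    # independent takeaway
    "comfort food", "independent_takeaway", 2L,
    "burger", "independent_takeaway", 2L,
    "chicken", "independent_takeaway", 2L,
    "fried chicken", "independent_takeaway", 2L,
    "fast food", "independent_takeaway", 4L,
    "kebab", "independent_takeaway", 2L,
    "fish and chips", "independent_takeaway", 2L,
    "pizza", "independent_takeaway", 2L,
    "family meals", "independent_takeaway", 2L,
    "american", "independent_takeaway", 2L,
    # independent restaurant / cafe
    "asian", "independent_restaurant_cafe", 2L,
    "japanese set item", "independent_restaurant_cafe", 1L,
    "italian", "independent_restaurant_cafe", 2L,
    "thai", "independent_restaurant_cafe", 2L,
    "indian", "independent_restaurant_cafe", 2L,
    "cafe", "independent_restaurant_cafe", 2L,
    "coffee", "independent_restaurant_cafe", 2L,
    "fine dining", "independent_restaurant_cafe", 1L,
    # multi-category descriptors
    "restaurant", "independent_restaurant_cafe", 2L,
    "restaurant", "independent_takeaway", 2L,
    "grocer", "supermarket_grocer", 2L,
    "grocer", "fresh_produce", 2L,
    "hotel", "alcohol_retailer", 2L,
    "hotel", "independent_restaurant_cafe", 2L,
    # sandwich / salad
    "salad", "sandwich_salad", 2L,
    "sandwich", "sandwich_salad", 2L,
    "sushi", "sandwich_salad", 2L,
    "healthy", "sandwich_salad", 2L,
    # supermarkets / grocers
    "supermarket", "supermarket_grocer", 2L,
    "grocery", "supermarket_grocer", 2L,
    # fresh produce
    "fruit and vegetables", "fresh_produce", 2L,
    "greengrocer", "fresh_produce", 2L,
    "butcher", "fresh_produce", 2L,
    "seafood market", "fresh_produce", 2L,
    # sweets / extra foods
    "dessert", "sweets_extra", 2L,
    "ice cream", "sweets_extra", 2L,
    "bubble tea", "sweets_extra", 2L,
    "sweets", "sweets_extra", 2L,
    "doughnuts", "sweets_extra", 2L,
    # bakery
    "bakery", "bakery", 2L,
    "patisserie", "bakery", 2L,
    "bread", "bakery", 2L,
    # convenience / petrol
    "convenience store", "convenience_petrol", 2L,
    "petrol station", "convenience_petrol", 2L,
    "service station", "convenience_petrol", 2L,
    # alcohol retail
    "bottle shop", "alcohol_retailer", 2L,
    "liquor store", "alcohol_retailer", 2L,
    # known non-food tags
    "jewelry store", NA_character_, 0L,
    "appliance store", NA_character_, 0L,
    "corporate office", NA_character_, 0L,
    "hardware store", NA_character_, 0L,
    "hair salon", NA_character_, 0L
  )
  if (!is.null(extra)) {
    lex <- bind_rows(lex, as_tibble(extra)) |>
      group_by(.data$descriptor, .data$category) |>
      slice_tail(n = 1) |>
      ungroup()
  }
  lex
}

#' Default franchise subtype lexicon
#'
#' Brand-level subtype assignments for known franchise brands; brands not
#' listed fall back to descriptor-keyword subtyping (see
#' [subtype_franchise()]).
#'
#' @return tibble with columns `brand`, `subtype`.
#' @export
default_subtype_lexicon <- function() {
  tribble(
    ~brand, ~subtype,
    "gelato galaxy", "dessert",
    "crust and crumb", "bakery",
    "juice junction", "juice",
    "green bowl", "healthy",
    "burger barn", "unhealthy",
    "chicken champion", "unhealthy",
    "pizza planet", "unhealthy"
  )
}

# Keyword lists for descriptor-based franchise subtyping, applied in fixed
# precedence order: dessert, bakery, juice, healthy, unhealthy (default).
subtype_keywords <- function() {
  list(
    dessert = c(
      "dessert", "ice cream", "gelato", "cake", "sweets", "bubble tea",
      "sugar sweetened beverages", "doughnuts"
    ),
    bakery = c("bakery", "bread", "pastries", "patisserie", "baked goods"),
    juice = c("juice", "smoothies", "smoothie"),
    healthy = c("salad", "salads", "sushi", "sandwich", "sandwiches", "healthy")
  )
}

#' Non-food category tags
#'
#' Directory category tags that mark a listing as an irrelevant non-food
#' business; a local row whose tags all fall in this list is filtered out.
#'
#' @return character vector of non-food tags.
#' @export
nonfood_tags <- function() {
  c(
    "jewelry store", "appliance store", "corporate office",
    "hardware store", "hair salon", "car dealership", "pharmacy",
    "clothing store", "gym"
  )
}
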