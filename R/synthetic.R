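#' Synthetic outlet universe and scraped-style listing views
#'
#' The synthetic-data layer fabricates a ground-truth universe of food
#' outlets over a [generate_geography()] lookup and renders the two noisy
#' "scraped" views the pipeline consumes: a local directory view (one row
#' per listed business, contaminated with non-food and permanently closed
#' listings) and an online delivery-platform view (one row per suburb each
#' platform outlet delivers to). Both renders return a truth map so that
#' linkage, filtering, and categorisation can be scored exactly.
#'
#' @name synthetic
NULL

# Word pools for generated entities. All tokens are lowercase alphanumeric
# words disjoint from the suburb/centre/petrol/state token lists, so text
# normalisation never mutilates a canonical name.
name_pool_first <- function() {
  c(
    "golden", "silver", "happy", "royal", "urban", "rustic", "cosy",
    "crimson", "velvet", "lucky", "jade", "amber", "sunny", "misty",
    "daily", "corner", "little", "grand", "olde", "blue", "red", "green",
    "white", "black", "spicy", "sweet", "fresh", "wild", "noble", "humble",
    "merry", "bright", "twin", "triple", "quiet", "rapid", "gentle",
    "proud", "brave", "calm"
  )
}

name_pool_second <- function() {
  c(
    "kitchen", "table", "spoon", "fork", "plate", "bowl", "pot", "pan",
    "grill", "oven", "hearth", "pantry", "larder", "deli", "eatery",
    "diner", "bistro", "canteen", "tavern", "shack", "hut", "nook", "den",
    "parlour", "house", "room", "bar", "stand", "stop", "wagon", "cart",
    "lounge", "terrace", "garden", "yard", "patio", "veranda", "court",
    "hall", "loft"
  )
}

street_name_pool <- function() {
  c(
    "main", "station", "church", "market", "school", "park", "bridge",
    "mill", "forest", "harbour", "victoria", "george", "william",
    "elizabeth", "margaret", "arthur", "edward", "albert", "young",
    "short", "crown", "king", "queen", "duke", "prince", "bay", "beach",
    "cliff", "valley", "meadow", "orchard", "summer", "winter", "autumn",
    "dawn", "dusk", "pioneer", "settler", "anchor", "compass"
  )
}

# Diagnostic descriptor pools per true category: `primary` descriptors map
# only to the category (so a single draw already decides the score),
# `extra` descriptors may be ambiguous.
category_descriptor_pool <- function() {
  list(
    independent_takeaway = list(
      primary = c(
        "comfort food", "burger", "chicken", "fried chicken", "kebab",
        "fish and chips", "pizza", "fast food"
      ),
      extra = "restaurant"
    ),
    independent_restaurant_cafe = list(
      primary = c("asian", "italian", "thai", "indian", "cafe", "coffee"),
      extra = "restaurant"
    ),
    sandwich_salad = list(primary = c("salad", "sandwich", "sushi"), extra = character()),
    supermarket_grocer = list(primary = c("supermarket", "grocery"), extra = "grocer"),
    fresh_produce = list(
      primary = c("fruit and vegetables", "greengrocer", "butcher", "seafood market"),
      extra = character()
    ),
    sweets_extra = list(
      primary = c("dessert", "ice cream", "bubble tea", "sweets", "doughnuts"),
      extra = character()
    ),
    bakery = list(primary = c("bakery", "patisserie", "bread"), extra = character()),
    convenience_petrol = list(
      primary = c("convenience store", "petrol station", "service station"),
      extra = character()
    ),
    alcohol_retailer = list(primary = c("bottle shop", "liquor store"), extra = character())
  )
}

franchise_descriptor_pool <- function() {
  list(
    unhealthy = c("fast food", "burger", "fried chicken", "pizza"),
    dessert = c("dessert", "ice cream", "bubble tea"),
    bakery = c("bakery", "bread", "patisserie"),
    juice = c("juice", "smoothies"),
    healthy = c("salad", "sushi", "sandwich")
  )
}

allocate_largest_remainder <- function(n, weights) {
  share <- weights / sum(weights)
  quota <- n * share
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the ground-truth outlet universe
#'
#' Fabricates outlets over a geography lookup: franchise brands are placed
#' first with their configured location counts (each brand in distinct
#' suburbs, so outlet identity is unambiguous), then independent outlets
#' fill each region's allocation, drawing a true category from the
#' configured category mix and descriptors diagnostic of it. Platform
#' participation is Bernoulli with the urban/rural probabilities of the
#' outlet's region.
#'
#' @param config a [sim_config()].
#' @param geography a [generate_geography()] tibble.
#' @param seed integer seed; the same seed yields an identical universe.
#' @return tibble of ground-truth outlets (one row per outlet) with columns
#'   `truth_id`, `brand`, `canonical_name`, `street_number`, `street_name`,
#'   `street_type`, `suburb`, `postcode`, `region`, `latitude`,
#'   `longitude`, `true_category`, `descriptors` (list), `is_food_business`,
#'   `is_open`, `on_delivery_platform`, `delivery_radius_km`.
#' @export
generate_universe <- function(config, geography, seed = 1L) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config()")
  if (nrow(geography) == 0) abort("geography must be non-empty")
  regions <- geography |>
    distinct(.data$region, .data$region_population, .data$urban)
  counts <- config$outlets_per_region
  if (is.null(counts)) {
    counts <- setNames(
      allocate_largest_remainder(config$n_outlets, regions$region_population),
      regions$region
    )
  } else {
    assert_that(all(names(counts) %in% regions$region), "unknown region in outlets_per_region")
    counts <- counts[regions$region]
    counts[is.na(counts)] <- 0L
    names(counts) <- regions$region
  }
  brands <- config$franchise_brands
  assert_that(
    nrow(brands) == 0 || max(brands$n_locations) <= nrow(geography),
    "a franchise brand has more locations than there are suburbs"
  )

  withr::with_seed(seed, {
    st_types <- c(
      "street", "road", "avenue", "lane", "drive",
      "parade", "place", "highway", "crescent", "boulevard"
    )
    quota <- counts
    fr_rows <- list()
    if (nrow(brands) > 0) {
      for (b in seq_len(nrow(brands))) {
        nb <- brands$n_locations[b]
        if (nb == 0) next
        w <- pmax(quota[geography$region], 0.01)
        pick <- sample(nrow(geography), nb, replace = FALSE, prob = w)
        subtype <- if ("subtype" %in% names(brands)) brands$subtype[b] else NA_character_
        is_franchise <- nb > 10
        cat <- if (is_franchise) "takeaway_franchise" else "independent_takeaway"
        dpool <- if (!is.na(subtype)) {
          franchise_descriptor_pool()[[subtype]]
        } else {
          category_descriptor_pool()$independent_takeaway$primary
        }
        fr_rows[[b]] <- tibble(
          brand = brands$brand[b],
          canonical_name = brands$brand[b],
          street_number = sample(1:300, nb, replace = TRUE),
          street_name = sample(street_name_pool(), nb, replace = TRUE),
          street_type = sample(st_types, nb, replace = TRUE),
          suburb = geography$suburb[pick],
          postcode = geography$postcode[pick],
          region = geography$region[pick],
          latitude = geography$latitude[pick] + runif(nb, -0.004, 0.004),
          longitude = geography$longitude[pick] + runif(nb, -0.004, 0.004),
          true_category = cat,
          descriptors = map(seq_len(nb), function(i) {
            sample(dpool, min(2, length(dpool)))
          })
        )
        tab <- table(geography$region[pick])
        quota[names(tab)] <- quota[names(tab)] - as.integer(tab)
      }
    }
    fr <- bind_rows(fr_rows)

    n_ind_region <- pmax(quota, 0L)
    n_ind <- sum(n_ind_region)
    combos <- sample(length(name_pool_first()) * length(name_pool_second()))
    ind_name <- function(i) {
      k <- combos[(i - 1) %% length(combos) + 1]
      nm <- paste(
        name_pool_first()[(k - 1) %% length(name_pool_first()) + 1],
        name_pool_second()[(k - 1) %/% length(name_pool_first()) + 1]
      )
      rep_n <- (i - 1) %/% length(combos)
      if (rep_n > 0) paste(nm, rep_n + 1) else nm
    }
    pools <- category_descriptor_pool()
    ind_rows <- list()
    i0 <- 0L
    for (r in names(n_ind_region)) {
      nr <- n_ind_region[[r]]
      if (nr == 0) next
      gsub_r <- geography[geography$region == r, ]
      pick <- sample(nrow(gsub_r), nr, replace = TRUE)
      cats <- sample(names(config$category_mix), nr, replace = TRUE, prob = config$category_mix)
      ind_rows[[r]] <- tibble(
        brand = NA_character_,
        canonical_name = map_chr(i0 + seq_len(nr), ind_name),
        street_number = sample(1:300, nr, replace = TRUE),
        street_name = sample(street_name_pool(), nr, replace = TRUE),
        street_type = sample(st_types, nr, replace = TRUE),
        suburb = gsub_r$suburb[pick],
        postcode = gsub_r$postcode[pick],
        region = r,
        latitude = gsub_r$latitude[pick] + runif(nr, -0.004, 0.004),
        longitude = gsub_r$longitude[pick] + runif(nr, -0.004, 0.004),
        true_category = cats,
        descriptors = map(cats, function(cc) {
          p <- pools[[cc]]
          d <- sample(p$primary, 1)
          if (length(p$primary) > 1 && runif(1) < 0.5) {
            d <- c(d, sample(setdiff(p$primary, d), 1))
          }
          if (length(p$extra) > 0 && runif(1) < 0.2) d <- c(d, sample(p$extra, 1))
          d
        })
      )
      i0 <- i0 + nr
    }
    universe <- bind_rows(fr, bind_rows(ind_rows))
    p_del <- ifelse(
      regions$urban[match(universe$region, regions$region)],
      config$p_delivery_urban, config$p_delivery_rural
    )
    universe |>
      mutate(
        truth_id = sprintf("T%05d", row_number()),
        is_food_business = TRUE,
        is_open = TRUE,
        on_delivery_platform = rbinom(n(), 1, p_del) == 1,
        delivery_radius_km = runif(
          n(), config$delivery_radius_range[1], config$delivery_radius_range[2]
        ),
        .before = 1
      )
  })
}

# Title-case a suburb for display noise.
display_case <- function(x) stringr::str_to_title(x)

# Apply the formatting-noise operators to one listing; draws come from the
# caller's substream. All operators are inverted by the normalisation rules
# (token-boundary punctuation, case changes, removable location tokens).
noisy_listing <- function(name, number, street_name, street_type,
                          suburb, postcode, noise, centres) {
  addr <- paste(number, street_name, street_type)
  if (runif(1) < noise$p_missing_street_number) {
    addr <- paste(street_name, street_type)
  }
  if (runif(1) < noise$p_centre_prefix) {
    addr <- paste0(
      "Shop ", sample(1:20, 1), ", ", display_case(sample(centres, 1)), ", ", addr
    )
  }
  if (runif(1) < noise$p_name_decoration) {
    addr <- paste(addr, display_case(suburb), "NSW", postcode)
  }
  if (runif(1) < noise$p_name_decoration) {
    name <- paste(name, sample(c(display_case(suburb), "Sydney", "NSW"), 1))
  }
  if (runif(1) < noise$p_punctuation) {
    op <- sample(c("excl", "quote", "dash", "period"), 1)
    name <- switch(op,
      excl = paste0(name, "!!"),
      quote = paste0("'", name, "'"),
      dash = sub(" ", " - ", name, fixed = TRUE),
      period = paste0(name, ".")
    )
  }
  if (runif(1) < noise$p_case_shuffle) {
    name <- if (runif(1) < 0.5) toupper(name) else stringr::str_to_title(name)
  }
  if (runif(1) < noise$p_missing_both) {
    suburb <- NA_character_
    postcode <- NA_character_
  } else {
    if (runif(1) < noise$p_missing_suburb) suburb <- NA_character_
    if (runif(1) < noise$p_missing_postcode) postcode <- NA_character_
  }
  list(name = name, street_address = addr, suburb = suburb, postcode = postcode)
}

nonfood_contaminant_names <- function() {
  c(
    "sparkle jewellers", "office hq", "bright appliances",
    "tool barn", "style cuts", "prestige motors"
  )
}

closed_contaminant_names <- function() {
  c("the old mill", "dusty diner", "bygone bites", "shuttered spoon")
}

#' Render the local directory view
#'
#' One raw listing row per universe outlet, with per-row noise from
#' seed-keyed substreams, plus contaminant rows at the configured rates:
#' non-food businesses (names/tags from a fixed list of appliance stores,
#' corporate offices, jewellers, and the like) and permanently closed
#' listings. A truth map links every rendered row to its truth id or a
#' contaminant tag.
#'
#' @param universe a [generate_universe()] tibble.
#' @param noise a [noise_config()].
#' @return list with `view` (raw listing tibble) and `truth`
#'   (`row_id`, `truth_id`, `contaminant`).
#' @export
render_local_view <- function(universe, noise = noise_config()) {
  if (nrow(universe) == 0) abort("universe must be non-empty")
  centres <- norm_config()$centre_list
  n <- nrow(universe)
  base <- map(seq_len(n), function(i) {
    u <- universe[i, ]
    with_substream(noise$seed, i, {
      nz <- noisy_listing(
        u$canonical_name, u$street_number, u$street_name, u$street_type,
        u$suburb, u$postcode, noise, centres
      )
      tibble(
        source = "local",
        source_id = sprintf("L%05d", i),
        row_id = sprintf("L%05d", i),
        name = nz$name,
        street_address = nz$street_address,
        suburb = nz$suburb,
        state = "NSW",
        postcode = nz$postcode,
        latitude = u$latitude,
        longitude = u$longitude,
        category_descriptors = u$descriptors,
        status = "open",
        delivery_suburb = NA_character_,
        truth_id = u$truth_id,
        contaminant = NA_character_
      )
    })
  }) |> bind_rows()

  geo_suburbs <- unique(universe$suburb)
  geo_postcodes <- unique(universe$postcode)
  contam <- map(seq_len(n), function(i) {
    with_substream(noise$seed, 2000000L + i, {
      rows <- list()
      if (runif(1) < noise$p_nonfood_rows) {
        rows$nf <- tibble(
          source = "local",
          source_id = sprintf("LN%05d", i),
          row_id = sprintf("LN%05d", i),
          name = display_case(sample(nonfood_contaminant_names(), 1)),
          street_address = paste(
            sample(1:300, 1), sample(street_name_pool(), 1), "street"
          ),
          suburb = sample(geo_suburbs, 1),
          state = "NSW",
          postcode = sample(geo_postcodes, 1),
          latitude = NA_real_,
          longitude = NA_real_,
          category_descriptors = list(sample(nonfood_tags(), sample(1:2, 1))),
          status = "open",
          delivery_suburb = NA_character_,
          truth_id = NA_character_,
          contaminant = "nonfood"
        )
      }
      if (runif(1) < noise$p_closed_rows) {
        rows$cl <- tibble(
          source = "local",
          source_id = sprintf("LC%05d", i),
          row_id = sprintf("LC%05d", i),
          name = display_case(sample(closed_contaminant_names(), 1)),
          street_address = paste(
            sample(1:300, 1), sample(street_name_pool(), 1), "road"
          ),
          suburb = sample(geo_suburbs, 1),
          state = "NSW",
          postcode = sample(geo_postcodes, 1),
          latitude = NA_real_,
          longitude = NA_real_,
          category_descriptors = list("restaurant"),
          status = "permanently_closed",
          delivery_suburb = NA_character_,
          truth_id = NA_character_,
          contaminant = "closed"
        )
      }
      bind_rows(rows)
    })
  }) |> bind_rows()

  view <- bind_rows(base, contam)
  list(
    view = view |> select(-"truth_id", -"contaminant"),
    truth = view |> select("row_id", "truth_id", "contaminant")
  )
}

#' Render the online delivery-platform view
#'
#' For every universe outlet on the delivery platform, emits one row per
#' suburb whose midpoint lies within the outlet's delivery radius
#' (equirectangular distance), so unique outlets appear once per delivery
#' suburb; an outlet whose radius covers no suburb midpoint still emits a
#' single row for its home suburb. All rows of an outlet share one platform
#' outlet id and one noisy render of the physical listing fields (a scraper
#' sees the same listing from every search suburb).
#'
#' @inheritParams render_local_view
#' @param geography the [generate_geography()] lookup supplying suburb
#'   midpoints.
#' @return list with `view` and `truth` tibbles as in [render_local_view()];
#'   the view carries `delivery_suburb` per row.
#' @export
render_online_view <- function(universe, geography, noise = noise_config()) {
  if (nrow(universe) == 0) abort("universe must be non-empty")
  centres <- norm_config()$centre_list
  idx <- which(universe$on_delivery_platform)
  rows <- map(idx, function(i) {
    u <- universe[i, ]
    d <- equirect_km(u$latitude, u$longitude, geography$latitude, geography$longitude)
    covered <- geography$suburb[d <= u$delivery_radius_km]
    if (length(covered) == 0) covered <- u$suburb
    covered <- covered[order(d[match(covered, geography$suburb)], covered)]
    with_substream(noise$seed, 3000000L + i, {
      nz <- noisy_listing(
        u$canonical_name, u$street_number, u$street_name, u$street_type,
        u$suburb, u$postcode, noise, centres
      )
      tibble(
        source = "online",
        source_id = sprintf("O%05d", i),
        row_id = sprintf("O%05d#%02d", i, seq_along(covered)),
        name = nz$name,
        street_address = nz$street_address,
        suburb = nz$suburb,
        state = "NSW",
        postcode = nz$postcode,
        latitude = u$latitude,
        longitude = u$longitude,
        category_descriptors = rep(list(u$descriptors[[1]]), length(covered)),
        status = "open",
        delivery_suburb = covered,
        truth_id = u$truth_id,
        contaminant = NA_character_
      )
    })
  }) |> bind_rows()
  if (nrow(rows) == 0) {
    rows <- tibble(
      source = character(), source_id = character(), row_id = character(),
      name = character(), street_address = character(), suburb = character(),
      state = character(), postcode = character(), latitude = numeric(),
      longitude = numeric(), category_descriptors = list(),
      status = character(), delivery_suburb = character(),
      truth_id = character(), contaminant = character()
    )
  }
  list(
    view = rows |> select(-"truth_id", -"contaminant"),
    truth = rows |> select("row_id", "truth_id", "contaminant")
  )
}
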