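#' Listing-text normalisation
#'
#' Cleaning rules that make the two listing sources comparable: lowercase,
#' diacritic stripping, punctuation removal, removal of embedded location
#' tokens (shopping centres, petrol stations, suburbs, city, state), street
#' address parsing against a closed street-type vocabulary, and
#' deterministic imputation of missing suburbs/postcodes/street numbers.
#' Every operation is idempotent and never touches `source` or
#' `source_id`.
#'
#' @name normalize
NULL

# Shared base scrub: ASCII-fold diacritics, spell out "&", lowercase,
# drop every non-alphanumeric character (no space inserted in its place),
# collapse whitespace. "Fish & Chips" and "Fish and Chips" meet here;
# "Brighton-Le-Sands" becomes "brightonlesands" (dashes deleted, spaces
# kept), which is deliberately NOT equal to "brighton le sands" — a
# documented failure mode of this family of cleaning rules, surfaced by
# the unmatched-outlet audit rather than papered over.
scrub_text <- function(x) {
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x <- str_replace_all(x, stringr::fixed("&"), " and ")
  x <- str_to_lower(x)
  x <- str_replace_all(x, "[^a-z0-9 ]", "")
  str_squish(x)
}

# Remove whole-word / whole-phrase occurrences of each token.
strip_tokens <- function(x, tokens) {
  tokens <- scrub_text(tokens)
  tokens <- tokens[nzchar(tokens)]
  for (tok in tokens) {
    x <- str_replace_all(x, paste0("\\b", tok, "\\b"), " ")
  }
  str_squish(x)
}

#' Normalise a suburb string
#'
#' Lowercases and removes special characters (dashes, quotes) while keeping
#' internal spaces, collapsing runs to single spaces. Rows whose state is
#' not the target state are rejected with the sentinel `"REJECT"`; missing
#' input stays missing (to be handled by imputation).
#'
#' @param raw_suburb character vector of raw suburb strings.
#' @param state character vector of raw state strings (recycled); `NA`
#'   states are not rejected.
#' @param config a [norm_config()].
#' @return character vector of normalised suburbs, `NA` for missing input,
#'   `"REJECT"` for out-of-state rows.
#' @export
#' @examples
#' normalize_suburb(c("SYDNEY", "Brighton-Le-Sands"), "NSW")
normalize_suburb <- function(raw_suburb, state = NA_character_, config = norm_config()) {
  state <- rep_len(state, length(raw_suburb))
  out <- scrub_text(raw_suburb)
  out[which(!is.na(out) & !nzchar(out))] <- NA_character_
  st <- scrub_text(state)
  reject <- !is.na(st) & nzchar(st) &
    !st %in% scrub_text(c(config$target_state, config$state_tokens))
  out[reject] <- "REJECT"
  out
}

#' Normalise an outlet name
#'
#' Lowercases, removes all non-alphanumeric characters, then removes
#' whole-word occurrences of shopping-centre names, petrol-station brands,
#' suburb names, the city token, and state tokens, in that order, and
#' collapses whitespace. A name that is empty after stripping is returned
#' as `""`; callers flag such rows for manual review rather than dropping
#' them.
#'
#' @param raw_name character vector of raw names.
#' @param config a [norm_config()] supplying the token lists.
#' @param suburbs character vector of suburb names to strip.
#' @return character vector of normalised names.
#' @export
#' @examples
#' normalize_name("Mario's Pizza!!")
#' normalize_name("Noodle House Sydney NSW")
normalize_name <- function(raw_name, config = norm_config(), suburbs = character()) {
  x <- scrub_text(raw_name)
  x <- strip_tokens(x, config$centre_list)
  x <- strip_tokens(x, config$petrol_list)
  x <- strip_tokens(x, suburbs)
  x <- strip_tokens(x, config$city_tokens)
  x <- strip_tokens(x, config$state_tokens)
  x
}

#' Parse a street address into number, street name, and street type
#'
#' Strips embedded suburb/postcode/state tokens and shopping-centre or
#' building prefixes (including leading "shop 12" / "unit 3" / "level 1"
#' tokens), maps street-type abbreviations to their canonical forms, then
#' splits the remainder into a leading number token, a street name, and a
#' trailing street-type token from the closed vocabulary. An address with
#' no leading number gets the sentinel street number `"12345"` and
#' `imputed_street_number = TRUE`; an unrecognised trailing token yields
#' street type `"unknown"` with the full remainder kept as the street name.
#'
#' @param raw_address character vector of raw street addresses.
#' @param suburb,postcode,state per-row location fields embedded copies of
#'   which are removed (recycled).
#' @param config a [norm_config()].
#' @param suburbs full suburb list whose tokens are removed from addresses.
#' @return tibble with `street_number`, `street_name`, `street_type`,
#'   `imputed_street_number`.
#' @export
#' @examples
#' parse_street_address("Shop 12, Westfield, 1 Main Street Parramatta NSW 2150",
#'   suburb = "Parramatta", postcode = "2150", state = "NSW"
#' )
parse_street_address <- function(raw_address, suburb = NA, postcode = NA,
                                 state = NA, config = norm_config(),
                                 suburbs = character()) {
  n <- length(raw_address)
  suburb <- rep_len(as.character(suburb), n)
  postcode <- rep_len(as.character(postcode), n)
  state <- rep_len(as.character(state), n)
  x <- scrub_text(raw_address)
  x <- strip_tokens(x, config$centre_list)
  # leading unit/shop/level tokens, possibly repeated
  x <- str_replace_all(x, "^((shop|unit|level|kiosk|suite) [0-9]+[a-z]? )+", "")
  x <- strip_tokens(x, c(config$state_tokens, suburbs))
  # per-row removal of this row's own embedded suburb/postcode/state tokens
  row_toks <- map_chr(seq_len(n), function(i) {
    toks <- scrub_text(c(suburb[i], postcode[i], state[i]))
    toks <- toks[!is.na(toks) & nzchar(toks)]
    if (length(toks) == 0) "" else paste0("\\b(", paste(toks, collapse = "|"), ")\\b")
  })
  has <- nzchar(row_toks)
  x[has] <- str_squish(stringr::str_replace_all(x[has], row_toks[has], " "))
  parts <- str_split(x, " ")
  res <- map(parts, function(p) {
    p <- p[nzchar(p)]
    imputed <- TRUE
    number <- "12345"
    if (length(p) > 0 && str_detect(p[1], "^[0-9]+[a-z]?$")) {
      number <- p[1]
      p <- p[-1]
      imputed <- FALSE
    }
    type <- "unknown"
    if (length(p) > 0) {
      last <- p[length(p)]
      if (!is.na(config$street_abbrev[last])) last <- config$street_abbrev[[last]]
      if (last %in% config$street_types) {
        type <- last
        p <- p[-length(p)]
      }
    }
    tibble(
      street_number = number,
      street_name = paste(p, collapse = " "),
      street_type = type,
      imputed_street_number = imputed
    )
  })
  bind_rows(res)
}

#' Normalise raw listings into structured outlet records
#'
#' Applies [normalize_suburb()], [normalize_name()], and
#' [parse_street_address()] row-wise and assembles the normalised record.
#' Rows rejected for being out of state carry `state_reject = TRUE` (the
#' cleaning wrappers drop them); names empty after stripping carry
#' `name_empty = TRUE` and are retained for the manual-review listing.
#' Postcode strings are kept only when they are exactly four digits;
#' anything else is treated as missing (and surfaces in the audit as a
#' malformed field). Imputation of missing suburbs/postcodes is a separate
#' pass, [impute_missing()], because the modal-suburb statistics must be
#' computed over the full combined dataset first.
#'
#' @param raw tibble of raw listings (see [render_local_view()] for the
#'   schema).
#' @param config a [norm_config()].
#' @param suburbs suburb token list for name/address stripping.
#' @return tibble of normalised outlets; `source` and `source_id` are
#'   carried through untouched, raw postcode/state kept as `postcode_raw`,
#'   `state_raw` for auditing.
#' @export
normalize_outlets <- function(raw, config = norm_config(), suburbs = character()) {
  suburb_norm <- normalize_suburb(raw$suburb, raw$state, config)
  addr <- parse_street_address(
    raw$street_address, raw$suburb, raw$postcode, raw$state, config, suburbs
  )
  pc <- str_squish(as.character(raw$postcode))
  pc[!is.na(pc) & !str_detect(pc, "^[0-9]{4}$")] <- NA_character_
  out <- tibble(
    source = raw$source,
    source_id = raw$source_id,
    name_norm = normalize_name(raw$name, config, suburbs),
    street_number = addr$street_number,
    street_name = addr$street_name,
    street_type = addr$street_type,
    suburb_norm = ifelse(suburb_norm == "REJECT", NA_character_, suburb_norm),
    postcode_norm = pc,
    imputed_suburb = FALSE,
    imputed_postcode = FALSE,
    imputed_street_number = addr$imputed_street_number,
    state_reject = !is.na(suburb_norm) & suburb_norm == "REJECT",
    name_empty = !nzchar(normalize_name(raw$name, config, suburbs)),
    descriptors = map(raw$category_descriptors, function(d) str_squish(str_to_lower(d))),
    latitude = raw$latitude,
    longitude = raw$longitude,
    postcode_raw = as.character(raw$postcode),
    state_raw = as.character(raw$state)
  )
  if ("delivery_suburb" %in% names(raw)) {
    out$delivery_suburb_norm <- normalize_suburb(raw$delivery_suburb, NA, config)
  }
  out
}

#' Modal suburb (and postcode) statistics for imputation
#'
#' Counts (postcode, suburb) co-occurrences over the combined dataset; the
#' modal suburb per postcode (ties broken lexicographically) fills missing
#' suburbs, and symmetrically the modal postcode per suburb fills missing
#' postcodes.
#'
#' @param ... normalised outlet tibbles to pool.
#' @return list with tibbles `suburb_by_postcode` and `postcode_by_suburb`.
#' @export
compute_suburb_stats <- function(...) {
  pooled <- bind_rows(...) |>
    filter(!is.na(.data$suburb_norm), !is.na(.data$postcode_norm)) |>
    count(.data$postcode_norm, .data$suburb_norm)
  list(
    suburb_by_postcode = pooled |>
      group_by(.data$postcode_norm) |>
      arrange(desc(.data$n), .data$suburb_norm, .by_group = TRUE) |>
      slice_head(n = 1) |>
      ungroup() |>
      select("postcode_norm", modal_suburb = "suburb_norm"),
    postcode_by_suburb = pooled |>
      group_by(.data$suburb_norm) |>
      arrange(desc(.data$n), .data$postcode_norm, .by_group = TRUE) |>
      slice_head(n = 1) |>
      ungroup() |>
      select("suburb_norm", modal_postcode = "postcode_norm")
  )
}

#' Impute missing suburbs and postcodes
#'
#' A missing suburb with a known postcode takes the modal suburb for that
#' postcode; a postcode present but unseen in the statistics leaves the
#' suburb as `"empty"` with the postcode kept. Rows missing both take
#' suburb `"empty"` and postcode `"0000"`. A missing postcode with a known
#' suburb takes the modal postcode for that suburb. Flags record every
#' imputation.
#'
#' @param records normalised outlet tibble.
#' @param stats output of [compute_suburb_stats()].
#' @return the records with `suburb_norm`, `postcode_norm` filled and
#'   imputation flags set.
#' @export
impute_missing <- function(records, stats) {
  sbp <- setNames(stats$suburb_by_postcode$modal_suburb, stats$suburb_by_postcode$postcode_norm)
  pbs <- setNames(stats$postcode_by_suburb$modal_postcode, stats$postcode_by_suburb$suburb_norm)
  records |>
    mutate(
      imputed_suburb = .data$imputed_suburb | is.na(.data$suburb_norm),
      imputed_postcode = .data$imputed_postcode | is.na(.data$postcode_norm),
      suburb_norm = case_when(
        !is.na(.data$suburb_norm) ~ .data$suburb_norm,
        is.na(.data$postcode_norm) ~ "empty",
        !is.na(sbp[.data$postcode_norm]) ~ unname(sbp[.data$postcode_norm]),
        .default = "empty"
      ),
      postcode_norm = case_when(
        !is.na(.data$postcode_norm) ~ .data$postcode_norm,
        .data$suburb_norm == "empty" ~ "0000",
        !is.na(pbs[.data$suburb_norm]) ~ unname(pbs[.data$suburb_norm]),
        .default = "0000"
      )
    )
}

#' Deduplicate the online view to one row per platform outlet
#'
#' Delivery-platform scrapes list an outlet once per suburb it delivers to;
#' unique outlets are identified by the platform outlet id. The
#' representative row is the one whose delivery suburb equals the outlet's
#' physical suburb when present, otherwise the first row in stable input
#' order. Conflicting physical addresses under one id keep the modal
#' address with a warning.
#'
#' @param rows raw online listing tibble.
#' @return tibble with one row per distinct `source_id`.
#' @export
dedupe_online <- function(rows) {
  if (nrow(rows) == 0) return(rows)
  conflicts <- rows |>
    distinct(.data$source_id, .data$street_address) |>
    count(.data$source_id) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    warn(paste0(
      nrow(conflicts), " platform id(s) carry conflicting physical addresses; keeping modal address"
    ))
    modal <- rows |>
      count(.data$source_id, .data$street_address) |>
      group_by(.data$source_id) |>
      arrange(desc(.data$n), .data$street_address, .by_group = TRUE) |>
      slice_head(n = 1) |>
      ungroup() |>
      select("source_id", modal_address = "street_address")
  }
  same <- function(a, b) {
    !is.na(a) & !is.na(b) & str_to_lower(str_squish(a)) == str_to_lower(str_squish(b))
  }
  reps <- rows |>
    mutate(.row = row_number(), .home = same(.data$delivery_suburb, .data$suburb)) |>
    group_by(.data$source_id) |>
    arrange(desc(.data$.home), .data$.row, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row", -".home")
  if (nrow(conflicts) > 0) {
    reps <- reps |>
      left_join(modal, by = "source_id") |>
      mutate(street_address = coalesce(.data$modal_address, .data$street_address)) |>
      select(-"modal_address")
  }
  reps
}

#' Filter the local view to open food businesses
#'
#' Removes listings tagged permanently closed and listings whose category
#' tags all map to the non-food list, then keeps one row per directory id.
#'
#' @param rows raw local listing tibble.
#' @param config a [norm_config()] supplying the non-food tag list.
#' @return filtered tibble.
#' @export
filter_local <- function(rows, config = norm_config()) {
  nf <- str_to_lower(config$nonfood)
  keep_food <- map_lgl(rows$category_descriptors, function(d) {
    d <- str_to_lower(str_squish(d))
    length(d) == 0 || !all(d %in% nf)
  })
  rows |>
    filter(.data$status != "permanently_closed", keep_food) |>
    distinct(.data$source_id, .keep_all = TRUE)
}
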