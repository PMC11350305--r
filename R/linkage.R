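#' The 15-step matching cascade specification
#'
#' Ordered matching rounds, each with looser criteria than the last.
#' Steps 1-9 require exact equality of the normalised name plus the listed
#' address fields; steps 10-11 drop name equality but require the name
#' Levenshtein ratio to reach the step 10/11 threshold (83 by default);
#' steps 12-15 block on a single address field and additionally require
#' name AND address similarity above the dual Jaro/ratio thresholds, as
#' does the final similarity pass run after step 15.
#'
#' @return tibble with columns `step`, `fields` (list of field names),
#'   `name_exact`, `name_min` (ratio threshold or `NA`), `dual_sim`.
#' @export
match_steps <- function() {
  f <- function(...) list(c(...))
  tribble(
    ~step, ~fields, ~name_exact, ~name_min, ~dual_sim,
    1L, f("name", "street_name", "suburb", "postcode"), TRUE, NA_real_, FALSE,
    2L, f("name", "street_name", "suburb"), TRUE, NA_real_, FALSE,
    3L, f("name", "street_name", "postcode"), TRUE, NA_real_, FALSE,
    4L, f("name", "postcode"), TRUE, NA_real_, FALSE,
    5L, f("name", "suburb"), TRUE, NA_real_, FALSE,
    6L, f("name", "street_name", "street_type"), TRUE, NA_real_, FALSE,
    7L, f("name", "suburb", "postcode"), TRUE, NA_real_, FALSE,
    8L, f("name", "street_number", "street_name"), TRUE, NA_real_, FALSE,
    9L, f("name", "street_number", "suburb", "postcode"), TRUE, NA_real_, FALSE,
    10L, f("street_number", "street_name", "suburb", "postcode"), FALSE, 83, FALSE,
    11L, f("street_name", "suburb", "postcode"), FALSE, 83, FALSE,
    12L, f("postcode"), FALSE, NA_real_, TRUE,
    13L, f("suburb"), FALSE, NA_real_, TRUE,
    14L, f("street_name"), FALSE, NA_real_, TRUE,
    15L, f("street_type"), FALSE, NA_real_, TRUE
  )
}

# Map the step-spec field names onto normalised-outlet columns and build
# the comparison pool: id, the six match fields, and the address string
# used for address similarity.
linkage_pool <- function(outlets) {
  tibble(
    id = outlets$source_id,
    name = outlets$name_norm,
    street_number = outlets$street_number,
    street_name = outlets$street_name,
    street_type = outlets$street_type,
    suburb = outlets$suburb_norm,
    postcode = outlets$postcode_norm,
    addr = str_squish(paste(
      outlets$street_number, outlets$street_name, outlets$street_type
    ))
  )
}

# Greedy one-to-one selection over scored candidate pairs: pairs are taken
# in order (online id, higher name ratio first, local id) and accepted when
# both sides are still free. Stable by construction, so permuting the input
# rows never changes the match set.
greedy_select <- function(cand) {
  cand <- cand |> arrange(.data$online_id, desc(.data$name_ratio), .data$local_id)
  taken_o <- new.env(parent = emptyenv())
  taken_l <- new.env(parent = emptyenv())
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    o <- cand$online_id[k]
    l <- cand$local_id[k]
    if (!exists(o, envir = taken_o) && !exists(l, envir = taken_l)) {
      keep[k] <- TRUE
      assign(o, TRUE, envir = taken_o)
      assign(l, TRUE, envir = taken_l)
    }
  }
  cand[keep, ]
}

#' Run the record-linkage cascade
#'
#' Executes the matching steps in order on deduplicated, normalised outlet
#' tables. Within a step, candidate pairs satisfying the step's
#' field-equality criteria (plus its similarity requirement, if any) are
#' matched greedily one-to-one in stable order of (online id, name ratio
#' descending, local id); matched rows leave both pools before the next
#' step. After step 15 a final similarity pass matches remaining pairs
#' whose name AND address similarities exceed the dual thresholds on both
#' scales. The recorded step is therefore the first step whose criteria
#' the pair satisfies.
#'
#' @param online,local normalised outlet tibbles ([normalize_outlets()] +
#'   [impute_missing()]), one row per outlet; duplicate ids are an error.
#' @param steps a [match_steps()] tibble.
#' @param thresholds a [similarity_thresholds()].
#' @param final_pass run the dual-threshold similarity pass after the last
#'   step (disable to study the step cascade in isolation).
#' @return an object of class `cascade_linkage`: list with `matches`
#'   (tibble: `online_id`, `local_id`, `step`, `name_similarity_jaro`,
#'   `name_similarity_ratio`, `address_similarity_ratio`),
#'   `unmatched_online`, `unmatched_local` (the input rows left unmatched),
#'   plus the inputs' sizes.
#' @export
run_cascade <- function(online, local, steps = match_steps(),
                        thresholds = similarity_thresholds(),
                        final_pass = TRUE) {
  if (anyDuplicated(online$source_id) || anyDuplicated(local$source_id)) {
    abort("duplicate source ids: inputs must be deduplicated upstream")
  }
  o_pool <- linkage_pool(online)
  l_pool <- linkage_pool(local)
  matches <- list()

  score_pairs <- function(cand) {
    cand |>
      mutate(
        name_ratio = lev_ratio(.data$name_o, .data$name_l),
        name_jaro = jaro_similarity(.data$name_o, .data$name_l),
        addr_ratio = lev_ratio(.data$addr_o, .data$addr_l),
        addr_jaro = jaro_similarity(.data$addr_o, .data$addr_l)
      )
  }
  dual_ok <- function(cand) {
    cand$name_jaro >= thresholds$jaro_min &
      cand$name_ratio >= thresholds$levenshtein_ratio_min &
      cand$addr_jaro >= thresholds$jaro_min &
      cand$addr_ratio >= thresholds$levenshtein_ratio_min
  }

  for (s in seq_len(nrow(steps))) {
    if (nrow(o_pool) == 0 || nrow(l_pool) == 0) break
    spec <- steps[s, ]
    by <- spec$fields[[1]]
    while (is.list(by)) by <- by[[1]]
    if (spec$name_exact) by <- union("name", by)
    keep_cols <- c("id", "name", "addr")
    cand <- inner_join(
      o_pool |> select(all_of(unique(c(keep_cols, by)))),
      l_pool |> select(all_of(unique(c(keep_cols, by)))),
      by = by, suffix = c("_o", "_l"),
      na_matches = "never", relationship = "many-to-many"
    ) |>
      rename(online_id = "id_o", local_id = "id_l")
    if (nrow(cand) == 0) next
    if ("name" %in% by) {
      cand <- cand |> mutate(name_o = .data$name, name_l = .data$name)
    }
    cand <- score_pairs(cand)
    if (!is.na(spec$name_min)) {
      cand <- cand |> filter(.data$name_ratio >= spec$name_min)
    }
    if (spec$dual_sim) {
      cand <- cand |> filter(dual_ok(cand))
    }
    if (nrow(cand) == 0) next
    sel <- greedy_select(cand)
    if (nrow(sel) == 0) next
    matches[[length(matches) + 1]] <- sel |>
      transmute(
        online_id = .data$online_id, local_id = .data$local_id,
        step = as.character(spec$step),
        name_similarity_jaro = .data$name_jaro,
        name_similarity_ratio = .data$name_ratio,
        address_similarity_ratio = .data$addr_ratio
      )
    o_pool <- o_pool |> filter(!.data$id %in% sel$online_id)
    l_pool <- l_pool |> filter(!.data$id %in% sel$local_id)
  }

  # final dual-threshold similarity pass over the remaining pools
  if (final_pass && nrow(o_pool) > 0 && nrow(l_pool) > 0) {
    cand <- tidyr::expand_grid(oi = seq_len(nrow(o_pool)), li = seq_len(nrow(l_pool))) |>
      mutate(
        online_id = o_pool$id[.data$oi], local_id = l_pool$id[.data$li],
        name_o = o_pool$name[.data$oi], name_l = l_pool$name[.data$li],
        addr_o = o_pool$addr[.data$oi], addr_l = l_pool$addr[.data$li]
      ) |>
      # cheap prune before the full four-way scoring
      mutate(name_ratio = lev_ratio(.data$name_o, .data$name_l)) |>
      filter(.data$name_ratio >= thresholds$levenshtein_ratio_min)
    if (nrow(cand) > 0) {
      cand <- cand |>
        mutate(
          name_jaro = jaro_similarity(.data$name_o, .data$name_l),
          addr_ratio = lev_ratio(.data$addr_o, .data$addr_l),
          addr_jaro = jaro_similarity(.data$addr_o, .data$addr_l)
        )
      cand <- cand[dual_ok(cand), ]
      sel <- greedy_select(cand)
      if (nrow(sel) > 0) {
        matches[[length(matches) + 1]] <- sel |>
          transmute(
            online_id = .data$online_id, local_id = .data$local_id,
            step = "similarity_pass",
            name_similarity_jaro = .data$name_jaro,
            name_similarity_ratio = .data$name_ratio,
            address_similarity_ratio = .data$addr_ratio
          )
        o_pool <- o_pool |> filter(!.data$id %in% sel$online_id)
        l_pool <- l_pool |> filter(!.data$id %in% sel$local_id)
      }
    }
  }

  matches <- if (length(matches) > 0) bind_rows(matches) else tibble(
    online_id = character(), local_id = character(), step = character(),
    name_similarity_jaro = numeric(), name_similarity_ratio = numeric(),
    address_similarity_ratio = numeric()
  )
  structure(
    list(
      matches = matches,
      unmatched_online = online |> filter(.data$source_id %in% o_pool$id),
      unmatched_local = local |> filter(.data$source_id %in% l_pool$id),
      n_online = nrow(online),
      n_local = nrow(local),
      thresholds = thresholds
    ),
    class = "cascade_linkage"
  )
}

#' @export
print.cascade_linkage <- function(x, ...) {
  cat(
    "<cascade_linkage> ", nrow(x$matches), " matches (",
    x$n_online, " online x ", x$n_local, " local); ",
    nrow(x$unmatched_online), " online unmatched\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname run_cascade
#' @param x a `cascade_linkage` object.
#' @param ... unused.
#' @method tidy cascade_linkage
#' @export
tidy.cascade_linkage <- function(x, ...) {
  x$matches
}

#' @rdname run_cascade
#' @method glance cascade_linkage
#' @export
glance.cascade_linkage <- function(x, ...) {
  tibble(
    n_online = x$n_online,
    n_local = x$n_local,
    n_matched = nrow(x$matches),
    match_rate = if (x$n_online > 0) nrow(x$matches) / x$n_online else NA_real_,
    n_unmatched_online = nrow(x$unmatched_online),
    n_unmatched_local = nrow(x$unmatched_local)
  )
}

#' Classify unmatched online outlets into an error taxonomy
#'
#' Advisory audit of why an online outlet found no local twin, mirroring
#' the failure modes seen when such linkages are verified manually:
#' malformed postcode/state columns, shopping-centre residue left in the
#' parsed address, suburb naming inconsistencies (the same suburb spelled
#' with and without spaces), near-miss names below the exact-match bar,
#' and genuinely platform-only outlets ("no_candidate").
#'
#' @param unmatched_online normalised online outlets left unmatched.
#' @param local the full normalised local table (matched and unmatched).
#' @param thresholds a [similarity_thresholds()].
#' @param config a [norm_config()] (centre list for residue detection).
#' @return tibble with `source_id` and `reason`.
#' @export
audit_unmatched <- function(unmatched_online, local,
                            thresholds = similarity_thresholds(),
                            config = norm_config()) {
  if (nrow(unmatched_online) == 0) {
    return(tibble(source_id = character(), reason = character()))
  }
  centre_words <- unique(unlist(str_split(scrub_text(config$centre_list), " ")))
  nospace <- function(x) str_replace_all(x, " ", "")
  l_name <- local$name_norm
  l_sub <- local$suburb_norm
  reasons <- map_chr(seq_len(nrow(unmatched_online)), function(i) {
    o <- unmatched_online[i, ]
    malformed <-
      (!is.na(o$postcode_raw) && !str_detect(str_squish(o$postcode_raw), "^[0-9]{4}$")) ||
        (!is.na(o$state_raw) && str_detect(o$state_raw, "[0-9]"))
    if (malformed) return("malformed_field")
    toks <- unlist(str_split(o$street_name, " "))
    if (any(toks %in% centre_words)) return("centre_residue")
    same_name <- !is.na(l_name) & l_name == o$name_norm
    if (isTRUE(any(same_name &
      !is.na(l_sub) & nospace(l_sub) == nospace(o$suburb_norm) &
      l_sub != o$suburb_norm, na.rm = TRUE))) {
      return("suburb_inconsistency")
    }
    ratio <- lev_ratio(rep(o$name_norm, length(l_name)), l_name)
    if (isTRUE(any(ratio >= thresholds$step10_11_name_min & ratio < 100, na.rm = TRUE))) {
      return("name_near_miss")
    }
    "no_candidate"
  })
  tibble(source_id = unmatched_online$source_id, reason = reasons)
}
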