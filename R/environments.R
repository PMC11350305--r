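#' Percent-change statistic for delivery-driven expansion
#'
#' The number of hybrid outlets divided by the number of local outlets,
#' multiplied by 100 and rounded half-up to an integer percent. Undefined
#' (`NA`) when there are no local outlets.
#'
#' @param n_local,n_hybrid outlet counts (vectorised).
#' @return integer percent vector.
#' @export
#' @examples
#' pct_change(10069, 13758) # 137
pct_change <- function(n_local, n_hybrid) {
  out <- ifelse(n_local > 0, round_half_up(100 * n_hybrid / n_local), NA_real_)
  as.integer(out)
}

#' Category share percentages
#'
#' `100 * count / total`, rounded half-up to one decimal; shares over a
#' partition sum to 100 within rounding slack.
#'
#' @param counts per-category counts.
#' @param total the partition total.
#' @return numeric vector of one-decimal percentages.
#' @export
#' @examples
#' category_share(17437, 36967) # 47.2
category_share <- function(counts, total) {
  round_half_up(100 * counts / total, 1)
}

#' Online accessibility of local outlets
#'
#' Share of local outlets of a category that are accessible online:
#' `100 * n_online / n_local`. Values above 100 are permitted (a category
#' can have more online than local listings). Both printing precisions are
#' exposed — one decimal and integer — since summary tables mix the two;
#' the renderer chooses.
#'
#' @param n_online,n_local counts (vectorised).
#' @return tibble `pct` (raw), `pct_1dp`, `pct_int`; `NA` when `n_local`
#'   is 0.
#' @export
#' @examples
#' online_accessibility(2734, 3273) # 83.5
#' online_accessibility(97, 45) # 216 on the integer scale
online_accessibility <- function(n_online, n_local) {
  pct <- ifelse(n_local > 0, 100 * n_online / n_local, NA_real_)
  tibble(
    pct = pct,
    pct_1dp = round_half_up(pct, 1),
    pct_int = as.integer(round_half_up(pct))
  )
}

region_of_postcode <- function(postcode, geography) {
  m <- geography |> distinct(.data$postcode, .data$region)
  out <- m$region[match(postcode, m$postcode)]
  ifelse(is.na(out), "unknown", out)
}

#' Assemble local, online, and hybrid environment views per geography unit
#'
#' The local view of a unit holds the food outlets physically located in
#' it; the online view holds the unique platform outlets that deliver into
#' it (from the delivery rows); the hybrid view is their union with
#' matched online/local pairs collapsed to a single outlet. Views are
#' built at both postcode and region level. Outlets whose postcode was
#' imputed to `"0000"` (or maps to no known unit) land in a reserved
#' `"unknown"` unit so totals stay conserved.
#'
#' @param local normalised, imputed local outlets.
#' @param online_rows the raw online view (one row per delivery suburb,
#'   with `source_id` and `delivery_suburb`).
#' @param matches matches tibble from [run_cascade()].
#' @param geography the geography lookup.
#' @return tibble of class `environment_views` with columns `unit_level`
#'   (`"postcode"`/`"region"`), `unit`, `scope` (`"local"`, `"online"`,
#'   `"hybrid"`), `n`, and `ids` (list of member outlet ids; hybrid ids
#'   are prefixed `L:`/`O:` after collapsing matched pairs onto the local
#'   id).
#' @export
build_views <- function(local, online_rows, matches, geography) {
  local_units <- tibble(
    id = local$source_id,
    postcode = ifelse(
      local$postcode_norm %in% geography$postcode, local$postcode_norm, "unknown"
    )
  ) |>
    mutate(region = region_of_postcode(.data$postcode, geography))

  online_units <- tibble(
    pid = online_rows$source_id,
    suburb = normalize_suburb(online_rows$delivery_suburb)
  ) |>
    left_join(
      geography |> select("suburb", "postcode", "region"),
      by = "suburb"
    ) |>
    mutate(
      postcode = coalesce(.data$postcode, "unknown"),
      region = coalesce(.data$region, "unknown")
    )

  twin <- setNames(matches$local_id, matches$online_id)
  canon <- function(pid) {
    if (length(pid) == 0) return(character())
    t <- twin[pid]
    ifelse(is.na(t), paste0("O:", pid), paste0("L:", unname(t)))
  }

  one_level <- function(level) {
    lu <- local_units |> rename(unit = all_of(level))
    ou <- online_units |> rename(unit = all_of(level))
    loc <- lu |>
      group_by(.data$unit) |>
      summarise(ids = list(unique(.data$id)), .groups = "drop") |>
      mutate(scope = "local")
    onl <- ou |>
      group_by(.data$unit) |>
      summarise(ids = list(unique(.data$pid)), .groups = "drop") |>
      mutate(scope = "online")
    hyb <- full_join(
      loc |> select("unit", local_ids = "ids"),
      onl |> select("unit", online_ids = "ids"),
      by = "unit"
    ) |>
      mutate(
        ids = map2(.data$local_ids, .data$online_ids, function(l, o) {
          if (is.null(l) || (length(l) == 1 && is.na(l[1]))) l <- character()
          if (is.null(o) || (length(o) == 1 && is.na(o[1]))) o <- character()
          # paste0 pads zero-length inputs to "", so guard explicitly
          lp <- if (length(l)) paste0("L:", l) else character()
          union(lp, canon(o))
        }),
        scope = "hybrid"
      ) |>
      select("unit", "ids", "scope")
    bind_rows(loc, onl, hyb) |>
      mutate(unit_level = level, n = map_int(.data$ids, length)) |>
      select("unit_level", "unit", "scope", "n", "ids")
  }

  out <- bind_rows(one_level("postcode"), one_level("region")) |>
    arrange(.data$unit_level, .data$unit, .data$scope)
  class(out) <- c("environment_views", class(out))
  out
}

#' State-wide unique outlet totals
#'
#' Unique-outlet totals across all units: local outlets count once (each
#' lives in one unit), online outlets count once per platform id however
#' many suburbs they deliver to, and the hybrid total collapses matched
#' pairs, so `n_hybrid = n_local + n_online - n_matched`.
#'
#' @inheritParams build_views
#' @return one-row tibble `n_local`, `n_online`, `n_matched`, `n_hybrid`,
#'   `pct_online_of_local`.
#' @export
environment_totals <- function(local, online_rows, matches) {
  n_local <- n_distinct(local$source_id)
  n_online <- n_distinct(online_rows$source_id)
  tibble(
    n_local = n_local,
    n_online = n_online,
    n_matched = nrow(matches),
    n_hybrid = n_local + n_online - nrow(matches),
    pct_online_of_local = category_share(n_online, n_local)
  )
}

#' Per-region summary with the percent-change statistic
#'
#' @param views an `environment_views` tibble from [build_views()].
#' @param geography the geography lookup.
#' @return tibble of class `region_summary`: `region`, `n_postcodes`,
#'   `population`, `n_local`, `n_online`, `n_hybrid`, `pct_change`.
#' @export
region_summary <- function(views, geography) {
  counts <- views |>
    filter(.data$unit_level == "region") |>
    select(region = "unit", "scope", "n") |>
    tidyr::pivot_wider(
      names_from = "scope", values_from = "n",
      names_prefix = "n_", values_fill = 0L
    )
  geo <- geography |>
    group_by(.data$region) |>
    summarise(
      n_postcodes = n_distinct(.data$postcode),
      population = first(.data$region_population),
      .groups = "drop"
    )
  out <- geo |>
    full_join(counts, by = "region") |>
    mutate(across(c("n_local", "n_online", "n_hybrid"), function(x) coalesce(x, 0L))) |>
    mutate(pct_change = pct_change(.data$n_local, .data$n_hybrid)) |>
    arrange(.data$n_local)
  class(out) <- c("region_summary", class(out))
  out
}

#' Category composition and online accessibility table
#'
#' State-wide counts and shares per main category for the local, online,
#' and hybrid environments, plus the online-accessibility column
#' (`n_online / n_local` per category). Matched pairs carry their online
#' twin's category, so per-category hybrid counts are
#' `n_local + n_online - n_matched` within the category. Set
#' `detail = "franchise_subtype"` for the franchise sub-rows.
#'
#' @param assignments output of [assign_categories()].
#' @param matches matches tibble.
#' @param detail `"main"` or `"franchise_subtype"`.
#' @return tibble with per-category counts, one-decimal shares, and both
#'   accessibility precisions.
#' @export
category_table <- function(assignments, matches, detail = c("main", "franchise_subtype")) {
  detail <- match.arg(detail)
  a <- assignments
  if (detail == "franchise_subtype") {
    a <- a |>
      filter(.data$main_category == "takeaway_franchise") |>
      mutate(group = .data$subtype)
  } else {
    a <- a |> mutate(group = coalesce(.data$main_category, "unassigned"))
  }
  matched_online <- a |>
    filter(.data$source == "online", .data$source_id %in% matches$online_id)
  tab <- a |>
    count(.data$group, source = .data$source) |>
    tidyr::pivot_wider(
      names_from = "source", values_from = "n",
      names_prefix = "n_", values_fill = 0L
    )
  for (col in c("n_local", "n_online")) if (!col %in% names(tab)) tab[[col]] <- 0L
  matched_n <- matched_online |> count(.data$group, name = "n_matched")
  tot_local <- sum(tab$n_local)
  tot_online <- sum(tab$n_online)
  out <- tab |>
    left_join(matched_n, by = "group") |>
    mutate(
      n_matched = coalesce(.data$n_matched, 0L),
      n_hybrid = .data$n_local + .data$n_online - .data$n_matched,
      share_local = category_share(.data$n_local, tot_local),
      share_online = category_share(.data$n_online, tot_online),
      share_hybrid = category_share(.data$n_hybrid, sum(.data$n_hybrid))
    )
  acc <- online_accessibility(out$n_online, out$n_local)
  out$accessibility_pct_1dp <- acc$pct_1dp
  out$accessibility_pct_int <- acc$pct_int
  out |> rename(category = "group")
}

#' Cuisine (descriptor) frequency table
#'
#' Counts each category descriptor over the scoped outlet set, descending,
#' ties broken lexicographically — the payload behind a cuisine word
#' cloud.
#'
#' @param outlets normalised outlets with a `descriptors` list column.
#' @return tibble `descriptor`, `n`.
#' @export
cuisine_frequencies <- function(outlets) {
  if (nrow(outlets) == 0) {
    return(tibble(descriptor = character(), n = integer()))
  }
  tibble(descriptor = unlist(outlets$descriptors)) |>
    mutate(descriptor = str_squish(str_to_lower(.data$descriptor))) |>
    count(.data$descriptor) |>
    arrange(desc(.data$n), .data$descriptor)
}

#' Relative outlet density per postcode
#'
#' Min-max scales per-postcode outlet counts of a scope to \[0, 1\] (the
#' choropleth shading scale). When all postcodes tie, every density is
#' defined as 1.
#'
#' @param views an `environment_views` tibble.
#' @param scope which scope to scale (default `"hybrid"`).
#' @return tibble `postcode`, `n`, `density`.
#' @export
density_by_postcode <- function(views, scope = "hybrid") {
  d <- views |>
    filter(.data$unit_level == "postcode", .data$scope == !!scope) |>
    select(postcode = "unit", "n")
  rng <- range(d$n)
  d |>
    mutate(density = if (rng[1] == rng[2]) 1.0 else (.data$n - rng[1]) / (rng[2] - rng[1]))
}
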