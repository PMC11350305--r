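test_that("percent change uses round-half-up of 100 * hybrid / local", {
  expect_equal(pct_change(10069, 13758), 137L)
  expect_equal(pct_change(893, 905), 101L)
  expect_equal(pct_change(299, 300), 100L)
  expect_equal(pct_change(2, 3), 150L)
  expect_equal(pct_change(200, 205), 103L) # 102.5 rounds up, not to even
  expect_true(is.na(pct_change(0, 10)))
})

test_that("category shares and accessibility reproduce printed-table arithmetic", {
  expect_equal(category_share(17437, 36967), 47.2)
  expect_equal(category_share(8369, 16158), 51.8)
  expect_equal(category_share(5, 5), 100)
  acc <- online_accessibility(2734, 3273)
  expect_equal(acc$pct_1dp, 83.5)
  acc <- online_accessibility(97, 45)
  expect_equal(acc$pct_int, 216L)
  expect_equal(online_accessibility(0, 50)$pct_1dp, 0)
  expect_true(is.na(online_accessibility(5, 0)$pct))
})

test_that("hybrid views union local and deliverable outlets, matched pairs once", {
  geography <- tibble(
    suburb = c("alpha", "beta"), postcode = c("2000", "2001"),
    region = "R01", region_population = 1000L, urban = TRUE,
    latitude = -34, longitude = 151
  )
  local <- dplyr::bind_rows(
    norm_row("L1", "a", suburb = "alpha", postcode = "2000", source = "local"),
    norm_row("L2", "b", suburb = "alpha", postcode = "2000", source = "local"),
    norm_row("L3", "c", suburb = "alpha", postcode = "2000", source = "local")
  )
  online_rows <- tibble(
    source_id = c("O1", "O1", "O2"),
    delivery_suburb = c("alpha", "beta", "alpha")
  )
  matches <- tibble(online_id = "O1", local_id = "L1")
  v <- build_views(local, online_rows, matches, geography)
  n_of <- function(unit, scope) v$n[v$unit_level == "postcode" & v$unit == unit & v$scope == scope]
  # 3 local + 2 deliverable - 1 matched pair = 4
  expect_equal(n_of("2000", "local"), 3L)
  expect_equal(n_of("2000", "online"), 2L)
  expect_equal(n_of("2000", "hybrid"), 4L)
  # unit with no local outlets: hybrid = deliverable outlets
  expect_equal(n_of("2001", "online"), 1L)
  expect_equal(n_of("2001", "hybrid"), 1L)
  # region level collapses both postcodes
  expect_equal(v$n[v$unit_level == "region" & v$scope == "hybrid"], 4L)
})

test_that("a unit with no online delivery has hybrid equal to local", {
  geography <- tibble(
    suburb = "alpha", postcode = "2000", region = "R01",
    region_population = 10L, urban = FALSE, latitude = -34, longitude = 151
  )
  local <- dplyr::bind_rows(
    norm_row("L1", "a", suburb = "alpha", postcode = "2000", source = "local"),
    norm_row("L2", "b", suburb = "alpha", postcode = "2000", source = "local")
  )
  online_rows <- tibble(source_id = character(), delivery_suburb = character())
  v <- build_views(local, online_rows, tibble(online_id = character(), local_id = character()), geography)
  expect_equal(
    v$n[v$unit == "2000" & v$scope == "hybrid"],
    v$n[v$unit == "2000" & v$scope == "local"]
  )
})

test_that("imputed-0000 outlets land in the reserved unknown unit, conserving totals", {
  geography <- tibble(
    suburb = "alpha", postcode = "2000", region = "R01",
    region_population = 10L, urban = FALSE, latitude = -34, longitude = 151
  )
  local <- dplyr::bind_rows(
    norm_row("L1", "a", suburb = "alpha", postcode = "2000", source = "local"),
    norm_row("L2", "b", suburb = "empty", postcode = "0000", source = "local")
  )
  v <- build_views(
    local, tibble(source_id = character(), delivery_suburb = character()),
    tibble(online_id = character(), local_id = character()), geography
  )
  loc <- v[v$unit_level == "postcode" & v$scope == "local", ]
  expect_setequal(loc$unit, c("2000", "unknown"))
  expect_equal(sum(loc$n), nrow(local))
})

test_that("synthetic hybrid counts equal the brute-force truth union", {
  run <- make_synthetic_run(n_outlets = 250, seed = 47)
  matches <- tidy(run_cascade(run$online, run$local))
  v <- build_views(run$local, run$online_raw, matches, run$geography)
  u <- run$universe
  # brute force from the truth layer: per postcode, physically-there union
  # delivered-there (participants whose radius covers a suburb of the unit)
  for (pc in unique(run$geography$postcode)) {
    subs <- run$geography[run$geography$postcode == pc, ]
    local_ids <- u$truth_id[u$postcode == pc]
    deliv <- vapply(seq_len(nrow(u)), function(i) {
      u$on_delivery_platform[i] &&
        any(equirect_km(u$latitude[i], u$longitude[i], subs$latitude, subs$longitude)
        <= u$delivery_radius_km[i])
    }, TRUE)
    expected <- length(union(local_ids, u$truth_id[deliv]))
    got <- v$n[v$unit_level == "postcode" & v$unit == pc & v$scope == "hybrid"]
    if (length(got) == 0) got <- 0L
    expect_equal(got, expected)
  }
})

test_that("per-view category counts are conserved and shares sum to 100", {
  run <- make_synthetic_run(n_outlets = 250, seed = 53)
  matches <- tidy(run_cascade(run$online, run$local))
  a <- assign_categories(run$local, run$online, matches)
  ct <- category_table(a, matches)
  expect_equal(sum(ct$n_local), nrow(run$local))
  expect_equal(sum(ct$n_online), nrow(run$online))
  expect_equal(sum(ct$n_hybrid), nrow(run$local) + nrow(run$online) - nrow(matches))
  expect_lt(abs(sum(ct$share_local) - 100), 0.5)
  expect_lt(abs(sum(ct$share_online) - 100), 0.5)
  expect_lt(abs(sum(ct$share_hybrid) - 100), 0.5)
  tot <- environment_totals(run$local, run$online_raw, matches)
  expect_equal(tot$n_hybrid, sum(ct$n_hybrid))
  # regional hybrid counts are bounded below by both scopes
  rs <- region_summary(
    build_views(run$local, run$online_raw, matches, run$geography),
    run$geography
  )
  expect_true(all(rs$n_hybrid >= pmax(rs$n_local, rs$n_online)))
  expect_true(all(rs$pct_change >= 100))
})

test_that("cuisine frequencies count descriptors descending with lexicographic ties", {
  outlets <- tibble(
    descriptors = list(c("burger", "salad"), "burger", "burger", "sushi")
  )
  f <- cuisine_frequencies(outlets)
  expect_equal(f$descriptor, c("burger", "salad", "sushi"))
  expect_equal(f$n, c(3L, 1L, 1L))
  expect_equal(nrow(cuisine_frequencies(outlets[0, ])), 0)
})

test_that("postcode density is min-max scaled with a degenerate case of 1", {
  mk_views <- function(counts) {
    v <- tibble(
      unit_level = "postcode", unit = names(counts), scope = "hybrid",
      n = unname(as.integer(counts)), ids = rep(list(character()), length(counts))
    )
    class(v) <- c("environment_views", class(v))
    v
  }
  d <- density_by_postcode(mk_views(c("2148" = 50, "2000" = 10, "2500" = 10)))
  expect_equal(d$density[d$postcode == "2148"], 1)
  expect_equal(d$density[d$postcode == "2000"], 0)
  d <- density_by_postcode(mk_views(c(a = 7, b = 7, c = 7)))
  expect_true(all(d$density == 1))
  # hand-scaled fixture
  d <- density_by_postcode(mk_views(c(a = 2, b = 6, c = 10)))
  expect_equal(d$density, c(0, 0.5, 1))
})
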