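test_that("descriptor scoring reproduces the worked takeaway example", {
  s <- score_categories(c("comfort food", "burger", "salad"))
  score_of <- function(cat) s$score[s$category == cat]
  expect_equal(score_of("independent_takeaway"), 4L)
  expect_equal(score_of("sandwich_salad"), 2L)
  a <- assign_main_category(s)
  expect_equal(a$main_category, "independent_takeaway")
  expect_false(a$tie_broken)
})

test_that("scoring covers base weights, adjusted weights, and multi-category descriptors", {
  s <- score_categories("asian")
  expect_equal(s$score[s$category == "independent_restaurant_cafe"], 2L)
  s <- score_categories("fast food")
  expect_equal(s$score[s$category == "independent_takeaway"], 4L)
  s <- score_categories("japanese set item")
  expect_equal(s$score[s$category == "independent_restaurant_cafe"], 1L)
  s <- score_categories("grocer")
  expect_equal(s$score[s$category == "supermarket_grocer"], 2L)
  expect_equal(s$score[s$category == "fresh_produce"], 2L)
  s <- score_categories("hotel")
  expect_equal(s$score[s$category == "alcohol_retailer"], 2L)
  expect_equal(s$score[s$category == "independent_restaurant_cafe"], 2L)
  # unknown descriptors and empty lists contribute nothing
  expect_equal(sum(score_categories(c("zzz unknown"))$score), 0L)
  expect_equal(sum(score_categories(character())$score), 0L)
})

test_that("scores are order-independent in the descriptor list", {
  d <- c("comfort food", "salad", "burger", "grocer")
  withr::with_seed(5, {
    for (i in 1:5) {
      expect_equal(score_categories(sample(d)), score_categories(d))
    }
  })
})

test_that("ties go to the globally rarer category, with a fixed fallback order", {
  s <- score_categories("grocer") # supermarket 2, fresh produce 2
  a <- assign_main_category(s, c(supermarket_grocer = 120L, fresh_produce = 30L))
  expect_equal(a$main_category, "fresh_produce")
  expect_true(a$tie_broken)
  a <- assign_main_category(s, c(supermarket_grocer = 10L, fresh_produce = 30L))
  expect_equal(a$main_category, "supermarket_grocer")
  # uniform frequencies: fixed category order decides
  a <- assign_main_category(s, c(supermarket_grocer = 5L, fresh_produce = 5L))
  expect_equal(a$main_category, "supermarket_grocer")
  expect_true(a$tie_broken)
  # all-zero scores stay unassigned
  a <- assign_main_category(score_categories("zzz"))
  expect_true(is.na(a$main_category))
})

test_that("franchise detection uses a strict >10 boundary and counts matched pairs once", {
  mk <- function(n, name, source = "local", id_prefix = "L") {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      norm_row(paste0(id_prefix, name, i), name,
        number = as.character(i),
        street = "main", suburb = "springvale", source = source
      )
    }))
  }
  ten <- mk(10, "ten chain")
  eleven <- mk(11, "eleven chain")
  reg <- detect_franchises(dplyr::bind_rows(ten, eleven))
  expect_equal(reg$brand, "eleven chain")
  expect_equal(reg$n_locations, 11L)

  # 10 local locations plus one matched online twin whose scraped address
  # differs: the matched pair counts once (10 locations, not a franchise);
  # ignoring the match would double-count the twin as an 11th location
  local10 <- mk(10, "border chain")
  online1 <- norm_row("Oborder1", "border chain", number = "99", street = "main")
  matches <- tibble(online_id = "Oborder1", local_id = "Lborder chain1")
  expect_equal(nrow(detect_franchises(dplyr::bind_rows(local10, online1), matches)), 0)
  expect_equal(nrow(detect_franchises(dplyr::bind_rows(local10, online1))), 1)
})

test_that("synthetic universes register exactly the configured franchise brands", {
  run <- make_synthetic_run(n_outlets = 250, seed = 41)
  matches <- tidy(run_cascade(run$online, run$local))
  reg <- detect_franchises(dplyr::bind_rows(run$online, run$local), matches)
  configured <- default_franchise_brands()
  expect_setequal(
    reg$brand,
    configured$brand[configured$n_locations > 10]
  )
  expect_equal(
    reg$n_locations[order(reg$brand)],
    configured$n_locations[configured$n_locations > 10][order(configured$brand[configured$n_locations > 10])]
  )
})

test_that("franchise subtyping: lexicon lookup with keyword-precedence fallback", {
  expect_equal(subtype_franchise("gelato galaxy"), "dessert")
  expect_equal(subtype_franchise("green bowl"), "healthy")
  fallback <- subtype_franchise(
    c("mystery burgers", "mystery greens", "mystery scoops"),
    brand_descriptors = list(
      "mystery burgers" = c("burger", "fried chicken"),
      "mystery greens" = c("salads", "sushi"),
      "mystery scoops" = c("ice cream", "salads")
    )
  )
  # dessert keywords take precedence over healthy ones
  expect_equal(fallback, c("unhealthy", "healthy", "dessert"))
})

test_that("matched local outlets inherit their online twin's category", {
  online <- dplyr::bind_rows(
    norm_row("O1", "shawarma today", descriptors = list(c("comfort food", "burger", "salad"))),
    norm_row("O2", "green grocer co", descriptors = list("supermarket"))
  )
  local <- dplyr::bind_rows(
    norm_row("L1", "shawarma today", source = "local", descriptors = list("salad")),
    norm_row("L2", "bread basket", source = "local", descriptors = list("bakery"))
  )
  matches <- tibble(online_id = "O1", local_id = "L1")
  a <- assign_categories(local, online, matches)
  l1 <- a[a$source_id == "L1" & a$source == "local", ]
  expect_equal(l1$main_category, "independent_takeaway")
  expect_equal(l1$assignment_source, "transferred")
  l2 <- a[a$source_id == "L2" & a$source == "local", ]
  expect_equal(l2$main_category, "bakery")
  expect_equal(l2$assignment_source, "scored")
})

test_that("full synthetic run: transfers, franchise labels, and one assignment each", {
  run <- make_synthetic_run(n_outlets = 250, seed = 43)
  matches <- tidy(run_cascade(run$online, run$local))
  a <- assign_categories(run$local, run$online, matches)
  expect_equal(nrow(a), nrow(run$local) + nrow(run$online))
  expect_equal(anyDuplicated(a[c("source", "source_id")]), 0L)
  # no matched local outlet retains a category conflicting with its twin
  twin <- a |>
    dplyr::filter(source == "online") |>
    dplyr::select(online_id = source_id, online_cat = main_category)
  check <- matches |>
    dplyr::left_join(twin, by = "online_id") |>
    dplyr::left_join(
      a |> dplyr::filter(source == "local") |>
        dplyr::select(local_id = source_id, local_cat = main_category),
      by = "local_id"
    )
  expect_equal(check$local_cat, check$online_cat)
  # every outlet ends with a main category, franchise subtype, or NA
  fr <- a[a$main_category %in% "takeaway_franchise", ]
  expect_true(all(fr$subtype %in% franchise_subtypes()))
  expect_true(all(is.na(a$subtype) | a$main_category == "takeaway_franchise"))
  # zero-noise scored assignments recover the true categories
  tr <- truth_of(
    a$source_id[a$source == "local"],
    run$local_truth
  )
  true_cat <- run$universe$true_category[match(tr, run$universe$truth_id)]
  expect_equal(a$main_category[a$source == "local"], true_cat)
})
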