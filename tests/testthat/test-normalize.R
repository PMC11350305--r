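test_that("suburb normalisation keeps spaces, removes specials, rejects other states", {
  expect_equal(normalize_suburb("SYDNEY", "NSW"), "sydney")
  # dashes are deleted without inserting spaces, so the two spellings of
  # the same suburb remain unequal -- a documented failure mode the
  # unmatched-outlet audit surfaces
  a <- normalize_suburb("Brighton-Le-Sands", "NSW")
  b <- normalize_suburb("Brighton Le Sands", "NSW")
  expect_equal(a, "brightonlesands")
  expect_equal(b, "brighton le sands")
  expect_false(a == b)
  expect_equal(normalize_suburb("Canberra", "ACT"), "REJECT")
  expect_equal(normalize_suburb("Bondi", "New South Wales"), "bondi")
  expect_true(is.na(normalize_suburb(NA_character_, "NSW")))
})

test_that("name normalisation strips punctuation and location tokens", {
  expect_equal(normalize_name("Mario's Pizza!!"), "marios pizza")
  expect_equal(normalize_name("Shawarma Today"), "shawarma today")
  expect_equal(normalize_name("Noodle House Sydney NSW"), "noodle house")
  expect_equal(normalize_name("Café Olé"), "cafe ole")
  expect_equal(normalize_name("Fish & Chips"), normalize_name("Fish and Chips"))
  expect_equal(normalize_name("7eleven Express"), "7eleven express")
  expect_equal(
    normalize_name("Westfield Noodle Bar", suburbs = "parramatta"),
    "noodle bar"
  )
  expect_equal(
    normalize_name("BP Hot Food", norm_config()),
    "hot food"
  )
  # empty after stripping is preserved as "" for manual review
  expect_equal(normalize_name("Sydney NSW"), "")
})

test_that("street address parsing handles centre prefixes, embeds, and sentinels", {
  p <- parse_street_address(
    "Shop 12, Westfield, 1 Main Street Parramatta NSW 2150",
    suburb = "Parramatta", postcode = "2150", state = "NSW"
  )
  expect_equal(p$street_number, "1")
  expect_equal(p$street_name, "main")
  expect_equal(p$street_type, "street")
  expect_false(p$imputed_street_number)

  p <- parse_street_address("5 King Road")
  expect_equal(unlist(p[1, 1:3], use.names = FALSE), c("5", "king", "road"))

  p <- parse_street_address("King Road")
  expect_equal(p$street_number, "12345")
  expect_true(p$imputed_street_number)
  expect_equal(p$street_name, "king")
  expect_equal(p$street_type, "road")
})

test_that("street address parsing matches a hand-parsed fixture set", {
  fixtures <- tibble::tribble(
    ~address, ~suburb, ~postcode, ~number, ~name, ~type,
    "12 George St", NA, NA, "12", "george", "street",
    "Unit 3 45 Harbour Rd Bondi", "Bondi", NA, "45", "harbour", "road",
    "221b Baker Street", NA, NA, "221b", "baker", "street",
    "Level 2 Central Park 7 Queen Ave", NA, NA, "7", "queen", "avenue",
    "88 Victoria Pde 2011", NA, "2011", "88", "victoria", "parade",
    "The Old Bakehouse", NA, NA, "12345", "the old bakehouse", "unknown",
    "3 Mill Lane New South Wales", NA, NA, "3", "mill", "lane",
    "Kiosk 5 9 Crown Cres", NA, NA, "9", "crown", "crescent"
  )
  p <- parse_street_address(
    fixtures$address, fixtures$suburb, fixtures$postcode, "NSW",
    suburbs = c("bondi")
  )
  expect_equal(p$street_number, fixtures$number)
  expect_equal(p$street_name, fixtures$name)
  expect_equal(p$street_type, fixtures$type)
})

test_that("normalisation operations are idempotent under fuzzing", {
  withr::with_seed(99, {
    charset <- c(letters, LETTERS, 0:9, " ", "'", "-", "&", "!", ".", ",", "é")
    raw <- replicate(200, paste(sample(charset, sample(0:25, 1), replace = TRUE), collapse = ""))
  })
  n1 <- normalize_name(raw)
  expect_equal(normalize_name(n1), n1)
  s1 <- normalize_suburb(raw)
  s2 <- normalize_suburb(s1)
  expect_equal(s2, s1)
  # parsing is stable when re-applied to its own reassembled output
  p1 <- parse_street_address(raw)
  addr1 <- trimws(paste(
    ifelse(p1$imputed_street_number, "", p1$street_number),
    p1$street_name,
    ifelse(p1$street_type == "unknown", "", p1$street_type)
  ))
  p2 <- parse_street_address(addr1)
  expect_equal(p2$street_name, p1$street_name)
  expect_equal(p2$street_type, p1$street_type)
})

test_that("imputation fills suburbs from the modal postcode association", {
  recs <- dplyr::bind_rows(
    norm_row("A1", "a", suburb = "sydney", postcode = "2000"),
    norm_row("A2", "b", suburb = "sydney", postcode = "2000"),
    norm_row("A3", "c", suburb = "haymarket", postcode = "2000"),
    norm_row("A4", "d", suburb = NA, postcode = "2000"),
    norm_row("A5", "e", suburb = NA, postcode = NA),
    norm_row("A6", "f", suburb = NA, postcode = "9999"),
    norm_row("A7", "g", suburb = "sydney", postcode = NA)
  )
  stats <- compute_suburb_stats(recs)
  out <- impute_missing(recs, stats)
  expect_equal(out$suburb_norm[4], "sydney") # modal beats haymarket
  expect_true(out$imputed_suburb[4])
  expect_equal(out$suburb_norm[5], "empty")
  expect_equal(out$postcode_norm[5], "0000")
  expect_equal(out$suburb_norm[6], "empty") # postcode unseen in stats
  expect_equal(out$postcode_norm[6], "9999")
  expect_equal(out$postcode_norm[7], "2000") # modal postcode for sydney
  # untouched rows keep values and flags
  expect_equal(out$suburb_norm[1:3], recs$suburb_norm[1:3])
  expect_false(any(out$imputed_suburb[1:3]))
})

test_that("modal-suburb ties break lexicographically", {
  recs <- dplyr::bind_rows(
    norm_row("B1", "a", suburb = "zetland", postcode = "2017"),
    norm_row("B2", "b", suburb = "beaconsfield", postcode = "2017")
  )
  stats <- compute_suburb_stats(recs)
  expect_equal(stats$suburb_by_postcode$modal_suburb, "beaconsfield")
})

test_that("online dedupe keeps one representative per platform id", {
  rows <- tibble(
    source = "online",
    source_id = c("P1", "P1", "P1", "P2", "P2", "P3", "P3"),
    row_id = paste0("r", 1:7),
    name = "x", street_address = "1 main street",
    suburb = c("alpha", "alpha", "alpha", "beta", "beta", "gamma", "gamma"),
    state = "NSW", postcode = "2000",
    latitude = NA_real_, longitude = NA_real_,
    category_descriptors = rep(list("cafe"), 7),
    status = "open",
    delivery_suburb = c("delta", "alpha", "echo", "echo", "zeta", "gamma", "beta")
  )
  out <- dedupe_online(rows)
  expect_equal(nrow(out), 3)
  # P1's representative is its physical-suburb row, P2 falls back to first
  expect_equal(out$delivery_suburb[out$source_id == "P1"], "alpha")
  expect_equal(out$delivery_suburb[out$source_id == "P2"], "echo")
  expect_equal(out$delivery_suburb[out$source_id == "P3"], "gamma")
})

test_that("conflicting addresses under one platform id keep the modal address", {
  rows <- tibble(
    source = "online", source_id = "P9", row_id = paste0("r", 1:3),
    name = "x", street_address = c("1 main street", "2 king road", "1 main street"),
    suburb = "alpha", state = "NSW", postcode = "2000",
    latitude = NA_real_, longitude = NA_real_,
    category_descriptors = rep(list("cafe"), 3), status = "open",
    delivery_suburb = c("beta", "gamma", "delta")
  )
  expect_warning(out <- dedupe_online(rows), "conflicting")
  expect_equal(out$street_address, "1 main street")
})

test_that("local filtering removes closed and all-non-food rows", {
  rows <- tibble(
    source = "local", source_id = paste0("L", 1:4), row_id = paste0("L", 1:4),
    name = c("Gem Shop", "Nice Cafe", "Gone Diner", "Mixed Use"),
    street_address = "1 main street", suburb = "alpha", state = "NSW",
    postcode = "2000", latitude = NA_real_, longitude = NA_real_,
    category_descriptors = list(
      "jewelry store", "cafe", "restaurant", c("jewelry store", "cafe")
    ),
    status = c("open", "open", "permanently_closed", "open"),
    delivery_suburb = NA_character_
  )
  out <- filter_local(rows)
  expect_setequal(out$source_id, c("L2", "L4"))
})

test_that("contaminated synthetic view filters back to the open food truth set", {
  run <- make_synthetic_run(
    n_outlets = 200, seed = 13,
    noise = noise_config(
      seed = 13, p_nonfood_rows = 0.15, p_closed_rows = 0.1,
      p_missing_suburb = 0, p_missing_postcode = 0, p_missing_both = 0,
      p_missing_street_number = 0, p_centre_prefix = 0,
      p_name_decoration = 0, p_case_shuffle = 0, p_punctuation = 0
    )
  )
  survivors <- run$local$source_id
  truth_ids <- run$local_truth$truth_id[match(survivors, run$local_truth$row_id)]
  expect_false(any(is.na(truth_ids)))
  expect_setequal(truth_ids, run$universe$truth_id)
})

test_that("normalisation never changes source or source_id", {
  run <- make_synthetic_run(n_outlets = 60, seed = 3, noise = noise_config(seed = 3))
  raw <- run$local_raw
  ncfg <- norm_config()
  out <- normalize_outlets(raw, ncfg, run$geography$suburb)
  expect_equal(out$source, raw$source)
  expect_equal(out$source_id, raw$source_id)
  # zero-noise dedupe conserves platform ids exactly
  expect_equal(
    nrow(dedupe_online(run$online_raw)),
    dplyr::n_distinct(run$online_raw$source_id)
  )
})
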