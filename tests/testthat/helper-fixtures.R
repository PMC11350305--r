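# Shared fixture builders: small synthetic datasets generated in code.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# Generate geography + universe + rendered views + cleaned tables in one go.
make_synthetic_run <- function(n_outlets = 300, seed = 1, noise = zero_noise(seed),
                               sim = sim_config(n_outlets = n_outlets),
                               geography = generate_geography()) {
  universe <- generate_universe(sim, geography, seed = seed)
  lr <- render_local_view(universe, noise)
  or <- render_online_view(universe, geography, noise)
  ncfg <- norm_config()
  local_f <- filter_local(lr$view, ncfg)
  online_d <- dedupe_online(or$view)
  local_n <- normalize_outlets(local_f, ncfg, geography$suburb) |>
    filter(!.data$state_reject)
  online_n <- normalize_outlets(online_d, ncfg, geography$suburb) |>
    filter(!.data$state_reject)
  stats <- compute_suburb_stats(local_n, online_n)
  list(
    geography = geography, universe = universe,
    local_raw = lr$view, local_truth = lr$truth,
    online_raw = or$view, online_truth = or$truth,
    local = impute_missing(local_n, stats),
    online = impute_missing(online_n, stats)
  )
}

# Truth id of each source row (local row ids and online platform ids map
# 1:1 onto truth ids through the truth tables).
truth_of <- function(ids, truth) {
  truth$truth_id[match(ids, substr(truth$row_id, 1, nchar(ids[1])))]
}

# Minimal normalised outlet tibble for hand-built linkage fixtures.
norm_row <- function(id, name, number = "1", street = "main", type = "street",
                     suburb = "springvale", postcode = "2000",
                     source = "online", descriptors = list("cafe")) {
  tibble(
    source = source, source_id = id, name_norm = name,
    street_number = number, street_name = street, street_type = type,
    suburb_norm = suburb, postcode_norm = postcode,
    imputed_suburb = FALSE, imputed_postcode = FALSE,
    imputed_street_number = number == "12345",
    state_reject = FALSE, name_empty = !nzchar(name),
    descriptors = descriptors,
    latitude = NA_real_, longitude = NA_real_,
    postcode_raw = postcode, state_raw = "NSW"
  )
}

sorted_matches <- function(m) {
  m <- as.data.frame(m)[, c("online_id", "local_id", "step")]
  m[order(m$online_id, m$local_id), , drop = FALSE] |> `rownames<-`(NULL)
}
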