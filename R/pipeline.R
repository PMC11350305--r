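#' Run the end-to-end pipeline
#'
#' Sequences the full analysis: simulate (geography, universe, the two
#' scraped-style views) -> clean (filter, dedupe, normalise, impute) ->
#' match (the cascade) -> categorize -> summarize (views, region summary,
#' category tables, cuisines, density) -> export (CSV, GeoJSON, word-cloud
#' JSON, manifest). Every stage's outputs are written under `outdir`; a
#' machine-readable `manifest.json` records the seed, a config hash, and
#' per-stage row counts. Re-running with the same config reproduces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with every intermediate object.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch(
    run_pipeline_stages(config, outdir),
    error = function(e) {
      abort(paste0("pipeline failed in stage [", attr(e, "fs_stage") %||% "?", "]: ",
                   conditionMessage(e)))
    }
  )
  invisible(res)
}

run_pipeline_stages <- function(config, outdir) {
  in_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      attr(e, "fs_stage") <- name
      stop(e)
    })
  }
  counts <- list()

  # -- simulate ------------------------------------------------------------
  sim <- in_stage("simulate", {
    geography <- do.call(generate_geography, config$geography)
    universe <- generate_universe(config$sim, geography, seed = config$seed)
    local_r <- render_local_view(universe, config$noise)
    online_r <- render_online_view(universe, geography, config$noise)
    list(
      geography = geography, universe = universe,
      local_raw = local_r$view, local_truth = local_r$truth,
      online_raw = online_r$view, online_truth = online_r$truth
    )
  })
  counts$universe <- nrow(sim$universe)
  counts$local_raw <- nrow(sim$local_raw)
  counts$online_raw <- nrow(sim$online_raw)

  # -- clean ---------------------------------------------------------------
  cln <- in_stage("clean", {
    ncfg <- norm_config()
    suburbs <- sim$geography$suburb
    local_f <- filter_local(sim$local_raw, ncfg)
    online_d <- dedupe_online(sim$online_raw)
    local_n <- normalize_outlets(local_f, ncfg, suburbs) |> filter(!.data$state_reject)
    online_n <- normalize_outlets(online_d, ncfg, suburbs) |> filter(!.data$state_reject)
    stats <- compute_suburb_stats(local_n, online_n)
    list(
      local = impute_missing(local_n, stats),
      online = impute_missing(online_n, stats)
    )
  })
  counts$local_clean <- nrow(cln$local)
  counts$online_clean <- nrow(cln$online)

  # -- match ---------------------------------------------------------------
  linkage <- in_stage("match", {
    run_cascade(cln$online, cln$local, match_steps(), config$thresholds)
  })
  counts$matched <- nrow(linkage$matches)
  audit <- in_stage("match", {
    audit_unmatched(linkage$unmatched_online, cln$local, config$thresholds)
  })

  # -- categorize ----------------------------------------------------------
  assignments <- in_stage("categorize", {
    assign_categories(
      cln$local, cln$online, linkage$matches,
      franchise_threshold = config$franchise_threshold
    )
  })
  counts$assigned <- nrow(assignments)

  # -- summarize -----------------------------------------------------------
  summ <- in_stage("summarize", {
    views <- build_views(cln$local, sim$online_raw, linkage$matches, sim$geography)
    list(
      views = views,
      totals = environment_totals(cln$local, sim$online_raw, linkage$matches),
      regions = region_summary(views, sim$geography),
      categories = category_table(assignments, linkage$matches),
      subtypes = category_table(assignments, linkage$matches, "franchise_subtype"),
      cuisines = cuisine_frequencies(bind_rows(cln$online, cln$local)),
      density = density_by_postcode(views)
    )
  })

  # -- export --------------------------------------------------------------
  in_stage("export", {
    write_outlets_csv(sim$geography, file.path(outdir, "geography.csv"))
    write_outlets_csv(sim$local_raw, file.path(outdir, "local_view.csv"))
    write_outlets_csv(sim$online_raw, file.path(outdir, "online_view.csv"))
    write_outlets_csv(sim$local_truth, file.path(outdir, "local_truth.csv"))
    write_outlets_csv(sim$online_truth, file.path(outdir, "online_truth.csv"))
    write_outlets_csv(cln$local, file.path(outdir, "local_clean.csv"))
    write_outlets_csv(cln$online, file.path(outdir, "online_clean.csv"))
    write_outlets_csv(linkage$matches, file.path(outdir, "matches.csv"))
    write_outlets_csv(audit, file.path(outdir, "unmatched_audit.csv"))
    write_outlets_csv(assignments, file.path(outdir, "assignments.csv"))
    write_outlets_csv(
      summ$views |> select(-"ids"), file.path(outdir, "environment_views.csv")
    )
    write_outlets_csv(summ$regions, file.path(outdir, "region_summary.csv"))
    write_outlets_csv(summ$categories, file.path(outdir, "category_table.csv"))
    write_outlets_csv(summ$subtypes, file.path(outdir, "franchise_subtypes.csv"))
    write_outlets_csv(summ$density, file.path(outdir, "density.csv"))
    export_postcode_geojson(summ$views, sim$geography, file.path(outdir, "postcodes.geojson"))
    write_wordcloud_json(summ$cuisines, file.path(outdir, "wordcloud.json"))
    manifest <- list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      row_counts = counts
    )
    jsonlite::write_json(
      manifest, file.path(outdir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })

  invisible(c(sim, cln, list(
    linkage = linkage, audit = audit, assignments = assignments
  ), summ))
}
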