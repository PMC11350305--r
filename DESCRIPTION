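Package: foodscape
Title: Record Linkage and Summaries of Local and Online Food Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the digitalisation of retail food
    environments from scraped-style outlet listings. Provides a synthetic
    generator for noisy directory and delivery-platform listing views with a
    known ground truth, text normalisation and address parsing rules for
    business listings, a deterministic stepwise record-linkage cascade with
    fuzzy name/address similarity passes, weighted descriptor scoring that
    assigns outlets to healthfulness-oriented main categories with
    rarity-based tie-breaking and franchise subtyping, and assembly of
    local, online, and hybrid food-environment summaries by postcode and
    region, with CSV/GeoJSON/JSON exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
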