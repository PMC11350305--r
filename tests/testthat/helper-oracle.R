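# Independent oracles used to check the package implementation.
#
# jaro_r: a pure-R Jaro similarity written directly from the textbook
# formula (matches within a window of floor(max(|a|,|b|)/2) - 1, half the
# transpositions), independent of the compiled implementation.
jaro_r <- function(a, b) {
  la <- nchar(a)
  lb <- nchar(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  window <- max(0, floor(max(la, lb) / 2) - 1)
  bmatched <- rep(FALSE, lb)
  amatch <- character()
  for (i in seq_len(la)) {
    lo <- max(1, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bmatched[j] && av[i] == bv[j]) {
        bmatched[j] <- TRUE
        amatch <- c(amatch, av[i])
        break
      }
    }
  }
  m <- length(amatch)
  if (m == 0) return(0)
  bmatch <- bv[bmatched]
  t <- sum(amatch != bmatch) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

# Levenshtein ratio oracle built on utils::adist (base R's C
# implementation), on the 0-100 scale used by the cascade.
lev_ratio_r <- function(a, b) {
  d <- as.numeric(utils::adist(a, b))
  mx <- max(nchar(a), nchar(b))
  if (mx == 0) 100 else 100 * (1 - d / mx)
}

# Brute-force cascade oracle: tests every (online, local) pair against
# every step in order, using comparison matrices rather than joins, with
# the same one-to-one greedy tie rule (online id, name ratio descending,
# local id). Jaro values come from jaro_r and are computed lazily.
oracle_cascade <- function(online, local, thresholds = similarity_thresholds()) {
  no <- nrow(online)
  nl <- nrow(local)
  addr <- function(df) {
    trimws(gsub(" +", " ", paste(df$street_number, df$street_name, df$street_type)))
  }
  o_addr <- addr(online)
  l_addr <- addr(local)
  ratio_mat <- function(a, b) {
    d <- utils::adist(a, b)
    mx <- outer(nchar(a), nchar(b), pmax)
    out <- 100 * (1 - d / mx)
    out[mx == 0] <- 100
    out
  }
  name_ratio <- ratio_mat(online$name_norm, local$name_norm)
  addr_ratio <- ratio_mat(o_addr, l_addr)
  eq <- function(a, b) {
    m <- outer(a, b, "==")
    m[is.na(m)] <- FALSE
    m
  }
  eqs <- list(
    name = eq(online$name_norm, local$name_norm),
    street_number = eq(online$street_number, local$street_number),
    street_name = eq(online$street_name, local$street_name),
    street_type = eq(online$street_type, local$street_type),
    suburb = eq(online$suburb_norm, local$suburb_norm),
    postcode = eq(online$postcode_norm, local$postcode_norm)
  )
  name_jaro <- matrix(NA_real_, no, nl)
  addr_jaro <- matrix(NA_real_, no, nl)
  get_jaro <- function(i, j, which) {
    m <- if (which == "name") name_jaro else addr_jaro
    if (is.na(m[i, j])) {
      v <- if (which == "name") {
        jaro_r(online$name_norm[i], local$name_norm[j])
      } else {
        jaro_r(o_addr[i], l_addr[j])
      }
      if (which == "name") name_jaro[i, j] <<- v else addr_jaro[i, j] <<- v
      v
    } else {
      m[i, j]
    }
  }
  dual_ok <- function(i, j) {
    name_ratio[i, j] >= thresholds$levenshtein_ratio_min &&
      addr_ratio[i, j] >= thresholds$levenshtein_ratio_min &&
      get_jaro(i, j, "name") >= thresholds$jaro_min &&
      get_jaro(i, j, "addr") >= thresholds$jaro_min
  }
  step_fields <- list(
    c("name", "street_name", "suburb", "postcode"),
    c("name", "street_name", "suburb"),
    c("name", "street_name", "postcode"),
    c("name", "postcode"),
    c("name", "suburb"),
    c("name", "street_name", "street_type"),
    c("name", "suburb", "postcode"),
    c("name", "street_number", "street_name"),
    c("name", "street_number", "suburb", "postcode"),
    c("street_number", "street_name", "suburb", "postcode"),
    c("street_name", "suburb", "postcode"),
    "postcode", "suburb", "street_name", "street_type"
  )
  o_free <- rep(TRUE, no)
  l_free <- rep(TRUE, nl)
  out <- list()
  run_round <- function(step_label, elig_fun) {
    cand <- which(outer(o_free, l_free, "&"), arr.ind = TRUE)
    if (nrow(cand) == 0) return(invisible())
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      keep[k] <- elig_fun(cand[k, 1], cand[k, 2])
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) return(invisible())
    df <- data.frame(
      oi = cand[, 1], li = cand[, 2],
      oid = online$source_id[cand[, 1]],
      lid = local$source_id[cand[, 2]],
      ratio = name_ratio[cand]
    )
    df <- df[order(df$oid, -df$ratio, df$lid), ]
    for (k in seq_len(nrow(df))) {
      if (o_free[df$oi[k]] && l_free[df$li[k]]) {
        o_free[df$oi[k]] <<- FALSE
        l_free[df$li[k]] <<- FALSE
        out[[length(out) + 1]] <<- data.frame(
          online_id = df$oid[k], local_id = df$lid[k], step = step_label
        )
      }
    }
  }
  for (s in seq_along(step_fields)) {
    fields <- step_fields[[s]]
    elig <- function(i, j) {
      for (f in fields) if (!eqs[[f]][i, j]) return(FALSE)
      if (s %in% 10:11 && name_ratio[i, j] < thresholds$step10_11_name_min) {
        return(FALSE)
      }
      if (s >= 12 && !dual_ok(i, j)) return(FALSE)
      TRUE
    }
    run_round(as.character(s), elig)
  }
  run_round("similarity_pass", dual_ok)
  if (length(out) == 0) {
    return(data.frame(online_id = character(), local_id = character(), step = character()))
  }
  do.call(rbind, out)
}
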