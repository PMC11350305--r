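#' Name and address string similarity on two scales
#'
#' Record pairs are compared on two scales side by side: the Jaro
#' similarity on \[0, 1\] (transposition-aware, well suited to short
#' names) and a normalised Levenshtein ratio on \[0, 100\], defined as
#' `100 * (1 - d / max(nchar(a), nchar(b)))` with `d` the unit-cost edit
#' distance. Both are symmetric; equal strings score (1, 100); an empty
#' string against a non-empty one scores (0, 0); two empty strings are
#' treated as equal.
#'
#' @param a,b character vectors (recycled to common length); inputs are
#'   expected to be normalised already.
#' @return tibble with columns `jaro` and `ratio`.
#' @export
#' @examples
#' name_similarity("martha", "marhta") # classic Jaro worked pair, 0.944
name_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  tibble(jaro = jaro_similarity(a, b), ratio = lev_ratio(a, b))
}

#' @rdname name_similarity
#' @export
jaro_similarity <- function(a, b) {
  jaro_sim_cpp(as.character(a), as.character(b))
}

#' @rdname name_similarity
#' @export
lev_ratio <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  d <- lev_dist_cpp(a, b)
  mx <- pmax(nchar(a), nchar(b))
  out <- ifelse(mx == 0, 100, 100 * (1 - d / mx))
  as.numeric(out)
}
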