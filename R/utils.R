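#' Round half away from zero
#'
#' Commercial ("round half up") rounding, used for all printed percentages:
#' `round_half_up(102.5) == 103`, unlike [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(100.5, 101.5, 47.15), c(0, 0, 1))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible 31-bit substream seed from a global seed and an
# integer key (row index, stage id). Keyed substreams make per-row noise
# independent of insertion order.
substream_seed <- function(seed, key) {
  s <- ((as.numeric(seed) %% 2147483647) * 48271) %% 2147483647
  k <- (as.numeric(key) * 1299721) %% 2147483647
  as.integer((s + k) %% 2147483647)
}

with_substream <- function(seed, key, code) {
  withr::with_seed(substream_seed(seed, key), code)
}

# Stage-name keys so each pipeline stage draws from its own stream.
stage_key <- function(stage) {
  sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
}

# Serialise a character list-column for CSV output and back.
pack_descriptors <- function(x) {
  map_chr(x, function(d) paste(d, collapse = "|"))
}

unpack_descriptors <- function(x) {
  map(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}
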