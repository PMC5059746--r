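# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

## All generators draw from an isolated RNG stream so that a fixed config
## seed yields identical output regardless of the caller's RNG state.
with_sim_seed <- function(seed, offset, code) {
  withr::with_seed(as.integer(seed) + as.integer(offset), code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)
}

## Random DNA as a character string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Split [0, len) into half-open tiles of size `tile` (last may be shorter).
tile_intervals <- function(len, tile) {
  starts <- seq(0, len - 1, by = tile)
  data.frame(start = starts, end = pmin(starts + tile, len))
}

## Overlap in bp between one interval and a vector of intervals (half-open).
overlap_bp <- function(start, end, starts, ends) {
  pmax(0, pmin(end, ends) - pmax(start, starts))
}
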