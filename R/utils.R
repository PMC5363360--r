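# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding used for presentation of overlap percentages: exact .5
#' values move away from zero (87.5 -> 88), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# 0-based condensed index of the unordered pair (i, j), i < j, among n items.
pair_index <- function(i, j, n) {
  stopifnot(all(i < j))
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

# Deterministic per-stage seed derived from a global seed and a stage name.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 1009 + h) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
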