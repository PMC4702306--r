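#' @keywords internal
"_PACKAGE"

## Seed substreams -----------------------------------------------------------

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in the simulator flows from one root seed. Each stage
#' (marker placement, meiosis, mating, phenotype noise, sequencing) draws its
#' own sub-seed from the root via a deterministic hash, so stages are
#' independently reproducible: re-running sequencing with a new spec does not
#' disturb the meioses.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @param index optional integer (e.g. replicate number) mixed into the hash.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
stage_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  h <- (h * 131 + as.numeric(index) %% m) %% m
  as.integer(h %% (m - 1L) + 1)
}

## Run-length helpers --------------------------------------------------------

# maximal runs of TRUE in a logical vector; returns two-column matrix (from, to)
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(from = starts[keep], to = ends[keep])
}

## Reporting helpers ---------------------------------------------------------

#' Round a width in base pairs to the nearest kilobase
#'
#' @param bp numeric base pairs.
#' @param nearest kilobase granularity: 1 rounds to the nearest kb, 10 to the
#'   nearest 10 kb.
#' @return numeric width in kb.
#' @export
round_kb <- function(bp, nearest = 1) {
  stopifnot(nearest > 0)
  round(bp / 1000 / nearest) * nearest
}

# internal: stable check for a whole-number scalar
is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
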