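# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a global seed
#'
#' All stochastic stages draw from independent substreams derived from one
#' global seed by a fixed affine map, so a single stage can be re-run in
#' isolation and still see exactly the stream it would see inside a full
#' pipeline run.
#'
#' @param seed Integer global seed.
#' @param stage One of `"array"`, `"qpcr"`, `"wapdg"`, `"pipeline"`,
#'   `"replicate"`.
#' @param index Optional non-negative replicate index, for loops that need a
#'   fresh substream per iteration.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage, index = 0L) {
  offsets <- c(array = 1, qpcr = 2, wapdg = 3, pipeline = 4, replicate = 5)
  if (!stage %in% names(offsets)) {
    stop("unknown stage '", stage, "'", call. = FALSE)
  }
  m <- 2147483587  # largest prime below 2^31 - 1 minus a margin; keeps seeds in int range
  s <- (as.numeric(seed) %% m + 97561 * offsets[[stage]] + 7919 * as.numeric(index)) %% m
  as.integer(s)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. Keeps package functions from clobbering user randomness.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
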