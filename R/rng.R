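#' Deterministic seed derivation and independent RNG substreams
#'
#' The whole pipeline is driven by one experiment seed. Per-stage seeds are
#' derived with a small polynomial hash of a human-readable tag, so adding a
#' strategy (or reordering stages) never perturbs another stage's randomness.
#' Substreams snapshot and restore `.Random.seed`, giving independent,
#' restartable streams for data order, task sampling, augmentation and
#' weight initialization.
#'
#' @param seed integer base seed (kept below 2^31).
#' @param tag character tag naming the consumer of the derived seed.
#' @return `derive_seed()`: a single integer in `[1, 2147483586]`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% 2147483587)
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483587
  as.integer(h + 1)
}

#' @rdname derive_seed
#' @keywords internal
rng_stream <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  st
}

#' @rdname derive_seed
#' @param stream a stream created by `rng_stream()`.
#' @param expr expression evaluated with the stream's RNG state active.
#' @keywords internal
with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
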