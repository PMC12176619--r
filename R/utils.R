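#' Derive a reproducible substream seed
#'
#' One user-facing seed drives the whole pipeline; each randomized stage
#' (event generation, spiking, plasticity, fold assignment, ...) derives its
#' own integer seed from the master seed and a stream name, so a stage can be
#' regenerated in isolation without replaying the streams before it.
#'
#' @param seed master integer seed.
#' @param stream character stream name, e.g. `"events"`, `"spikes"`.
#' @return an integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # 31-bit multiplicative string hash, folded with the master seed
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

#' Evaluate an expression under a named RNG substream
#'
#' Saves and restores the caller's RNG state, so substream draws never
#' perturb unrelated randomness.
#' @param seed master seed.
#' @param stream stream name.
#' @param expr expression to evaluate.
#' @keywords internal
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(substream_seed(seed, stream))
  expr
}

# stop() with a consistent condition class so callers can distinguish
# invalid-input errors from numerical failures
.invalid_input <- function(msg) {
  stop(errorCondition(msg, class = c("cfareact_invalid_input", "error")))
}

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .invalid_input(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) {
    .invalid_input(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}
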