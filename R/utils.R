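# Internal helpers shared across modules.

# ms -> sample offset under the package-wide convention: 0-based sample
# indices, offset = round(ms * fs / 1000).
ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

samples_to_ms <- function(s, fs) s * 1000 / fs

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Run a block with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so simulations never disturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic participant-level seed derived from the cohort seed, kept
# strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1299721) %% 2147483647)
}
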