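# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never clobber
# the user's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic derived seed in [1, 2^31 - 2]; a simple LCG-style hash of
# (master, index) so per-lesion / per-task streams are reproducible and
# non-overlapping in practice.
derive_seed <- function(master, index) {
  m <- 2147483647
  h <- (as.double(master) %% m) * 48271 + as.double(index) * 104729 + 1
  as.integer(h %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
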