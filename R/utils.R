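# Internal helpers: seeded evaluation that restores the caller's RNG state,
# and derivation of per-patient child seeds from one master seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under `set.seed(seed)`; the global RNG state present on
# entry is restored on exit so seeded helpers never perturb caller RNG.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Splitmix-style integer derivation: reproducible child streams (patients,
# folds, ensemble members) from one master seed. All arithmetic stays well
# below 2^53 so doubles are exact; result is in [1, 2^31 - 2].
child_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 100000) * 19349663 + as.numeric(i) * 40503 + 7919
  as.integer(s %% 2147483646) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

BEAT_CLASSES <- c("N", "S", "V")
SEGMENT_TYPES <- c("P", "QRS", "T")
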