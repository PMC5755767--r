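# internal helpers shared across modules

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pivcomm_error")))
}

# Run `code` under a fixed seed, then restore the caller's RNG state so that
# library internals never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed expansion from one user-facing seed.
# Offsets keep every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  offsets <- c(scan = 101L, boot = 211L, entropy = 307L, dice = 401L,
               null = 503L, simulate = 601L)
  stopifnot(stage %in% names(offsets))
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
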