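# Run expr under set.seed(seed) without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Spawn `n` stage seeds deterministically from one master seed.
derive_seeds <- function(master_seed, n) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# canonical 0/1 string encoding of a mask (fast path: one raw conversion)
mask_key <- function(mask) rawToChar(as.raw(48L + as.integer(mask)))
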