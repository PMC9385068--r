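# Seed plumbing: every stochastic entry point takes a `seed` argument and
# runs under a locally scoped RNG state, so calls are reproducible without
# disturbing the caller's random stream. Sub-seeds for (repetition, cell,
# device) are derived with a small counter-based mix kept below 2^31.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in as.double(c(...)))
    s <- (s * 69069 + k * 7919 + 12345) %% 2147483647
  as.integer(s)
}

# Stable small hash of a device id string, for per-device sub-seeds.
id_hash <- function(id) {
  v <- utf8ToInt(as.character(id))
  s <- 0
  for (ch in v) s <- (s * 31 + ch) %% 1000003
  s
}
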