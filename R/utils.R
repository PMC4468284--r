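# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 69621) %% 2147483563) + 1L
}
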