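# Small shared helpers.

sigmoid <- function(z) 1 / (1 + exp(-z))

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Soft-threshold operator used by the proximal l1 update.
soft_threshold <- function(w, thr) sign(w) * pmax(abs(w) - thr, 0)
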