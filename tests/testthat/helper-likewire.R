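# Small deterministic fixtures shared across test files.

quick_anatomy <- function(seed = 1, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  generate_anatomy(generate_population(cfg))
}

# independent Ld oracle: brute-force proximal pairs + direct edge sum
oracle_ld <- function(axon, dend, radius = 5) {
  axon <- discretize_skeleton(axon, 1)
  dend <- discretize_skeleton(dend, 1)
  pairs <- find_proximities_brute(axon, dend, radius)
  if (nrow(pairs) == 0L) return(0)
  prox <- unique(pairs[, 2L])
  v <- dend$vertices
  keep <- dend$edges[, 1L] %in% prox | dend$edges[, 2L] %in% prox
  e <- dend$edges[keep, , drop = FALSE]
  sum(sqrt(rowSums((v[e[, 1L], , drop = FALSE] -
                      v[e[, 2L], , drop = FALSE])^2)))
}
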