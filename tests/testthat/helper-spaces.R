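## Cached genotype spaces shared across test files (built once per run).

.space_cache <- new.env(parent = emptyenv())

omega_k <- function(k) {
  key <- paste0("k", k)
  if (is.null(.space_cache[[key]]))
    .space_cache[[key]] <- build_omega(k)
  .space_cache[[key]]
}

omega4 <- function() omega_k(4)
omega8 <- function() omega_k(8)

## small synthetic landscape on the k = 4 space: three overlapping
## phenotypes, deterministic
toy_networks4 <- function(seed = 42, n_tfs = 3, noise_sd = 0.02) {
  om <- omega4()
  spec <- synthetic_spec(n_tfs = n_tfs, k = 4, seed = seed,
                         base_score = 0.45, decay = 0.05,
                         noise_sd = noise_sd)
  gen <- generate_escore_table(spec, om)
  list(omega = om, table = gen$table, meta = gen$meta, truth = gen$truth,
       networks = dominant_networks(gen$table, om))
}
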