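# Sweep fixtures are expensive; compute each at most once per test session.

.sweep_cache <- new.env(parent = emptyenv())

cached_core_sweep <- function() {
  if (is.null(.sweep_cache$core))
    .sweep_cache$core <- run_core_sweep(seed = 1)
  .sweep_cache$core
}

cached_expanded_sweep <- function() {
  if (is.null(.sweep_cache$expanded))
    .sweep_cache$expanded <- run_expanded_sweep(seed = 1, draws_per_cell = 24,
                                                M = 1)
  .sweep_cache$expanded
}
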