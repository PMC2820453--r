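# Shared simulation settings for tests: same architecture as the default
# (58-gene island, 11 operons / 52 genes, 49 kb span) on a smaller
# genome so individual tests stay fast.

tiny_spec <- function(seed = 42, ...) {
  simulation_spec(n_genes = 150,
                  island = list(start_index = 40, n_island_genes = 58,
                                n_regulon_in_island = 52,
                                operon_structure = c(5, 2, 7, 3, 8, 2, 5, 6,
                                                     1, 4, 9),
                                span_bp = 49000),
                  n_regulon_outside = 20, seed = seed, ...)
}

# cached default instances (the specs are deterministic, so sharing one
# realisation across test files is safe)
tiny_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(tiny_spec())
    cache
  }
})

micro_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(micro_spec())
    cache
  }
})

# smallest layout that still has operons, gap genes and outside members
micro_spec <- function(seed = 42, ...) {
  simulation_spec(n_genes = 30,
                  island = list(start_index = 10, n_island_genes = 12,
                                n_regulon_in_island = 10,
                                operon_structure = c(4, 6),
                                span_bp = 10000),
                  n_regulon_outside = 2, seed = seed, ...)
}
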