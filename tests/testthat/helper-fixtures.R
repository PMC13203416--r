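# Lazily built, memoized fixtures shared across test files. Everything is
# generated in code under fixed seeds; nothing is read from disk.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_ch <- function() fixture("ch", function() {
  generate_genome(synthetic_spec("CH", seed = 101L))
})

fx_trio <- function() fixture("trio", function() synthetic_trio(seed = 201L))

fx_evolved <- function() fixture("evolved", function() evolved_trio(seed = 301L))

random_seq <- function(n, seed) {
  mitochar:::with_seed(seed, mitochar:::random_dna(n))
}

# A tiny hand-made circular genome used by coordinate-convention tests.
tiny_genome <- function() {
  feats <- gene_features(
    name = c("geneA", "geneB", "geneC"),
    type = c("PCG", "tRNA", "control_region"),
    start = c(3L, 19L, 27L),
    end = c(17L, 26L, 2L),          # geneC wraps the origin
    strand = c("H", "L", "H"))
  mito_genome("tiny", "ATGGCACGTACGGCATAAGGCCTTAAGTCT", feats,
              circular = TRUE)
}
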