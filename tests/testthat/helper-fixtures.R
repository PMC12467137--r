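## Small simulated worlds shared across test files; built in code at test
## time, never stored.

tiny_reference <- function(seed = 1, ...) {
  simulate_reference(n_chrom = 1, chrom_length = 40000, n_genes = 8,
                     n_mirnas = 5, n_circ = 4, seed = seed, ...)
}

tiny_planted <- function(seed = 1, n_triples = 2) {
  ref <- tiny_reference(seed)
  plant_regulation(ref, n_triples = n_triples, seed = seed + 1000)
}

## a one-gene, one-circ genome built by hand for fully controlled caller
## tests: the circle is [200, 500) on a 2 kb chromosome
handmade_world <- function(seed = 7) {
  set.seed(seed)
  g <- random_dna_str(2000)
  ## pin the junction so leftmost-acceptor calling is exact
  last <- substr(g, 500, 500)       # 0-based 499 = d - 1
  up <- substr(g, 200, 200)         # 0-based 199 = a - 1
  if (up == last) {
    repl <- setdiff(c("A", "C", "G", "T"), last)[1]
    g <- paste0(substr(g, 1, 199), repl, substr(g, 201, 2000))
  }
  list(genome = c(chr1 = g), start = 200L, end = 500L)
}

## junction-spanning read with `p` donor-side bases
handmade_junction_read <- function(world, p = 50, read_len = 100) {
  span <- substr(world$genome[["chr1"]], world$start + 1L, world$end)
  doubled <- paste0(span, span)
  substr(doubled, nchar(span) - p + 1L, nchar(span) - p + read_len)
}
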