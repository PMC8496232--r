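# shared small fixtures, built once per test run
fixture_env <- new.env(parent = emptyenv())

small_cross <- function() {
  if (is.null(fixture_env$cross)) {
    map <- sim_genetic_map(n_chromosomes = 3, markers_per_chromosome = 20,
                           chrom_length_cM = 75, seed = 101)
    geno <- sim_cross_genotypes(map, n_offspring = 120, seed = 102)
    X <- encode_design(geno, map)
    fixture_env$cross <- list(map = map, geno = geno, X = X)
  }
  fixture_env$cross
}

# a deterministic one-chromosome map with markers every `by` cM
toy_map <- function(m, by = 1, chrom = "chr01") {
  tibble::tibble(
    marker = sprintf("m%03d", seq_len(m)),
    chrom = chrom,
    pos_cM = (seq_len(m) - 1) * by,
    pos_bp = as.integer((seq_len(m) - 1) * by * 1e5 + 1)
  )
}
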