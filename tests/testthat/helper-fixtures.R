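# Fixture builders shared across test files. All fixtures are generated
# in code under fixed seeds; nothing is read from disk.

random_counts <- function(g, c, lambda = 5, seed = 1) {
  set.seed(seed)
  as_expression_matrix(matrix(rpois(g * c, lambda), g, c))
}

# A cloud of paired (duplicated) cells plus one cell whose profile is
# 100x everything else. Every cloud cell has an exact twin, so its
# nearest distance is 0 while the planted cell sits far away: the
# quartile rule flags the planted cell and nothing else.
planted_outlier_matrix <- function(n_genes = 50, n_pairs = 10, seed = 3) {
  set.seed(seed)
  profiles <- matrix(rpois(n_genes * n_pairs, 100), n_genes, n_pairs)
  m <- cbind(profiles[, rep(seq_len(n_pairs), each = 2)],
             profiles[, 1] * 100)
  as_expression_matrix(m)
}

# Two clearly separated planted cell types.
two_type_matrix <- function(n_genes = 100, per_type = 15, seed = 5,
                            shift = 50) {
  set.seed(seed)
  a <- matrix(rpois(n_genes * per_type, 5), n_genes, per_type)
  b <- matrix(rpois(n_genes * per_type, 5), n_genes, per_type)
  b[seq_len(n_genes / 2), ] <- b[seq_len(n_genes / 2), ] + shift
  m <- as_expression_matrix(cbind(a, b))
  list(matrix = m, labels = rep(c("A", "B"), each = per_type))
}

# A small dataset in the simulator's regime, cheap enough for unit tests.
small_sim <- function(seed = 1, n_genes = 600, n_cells = 45) {
  simulate_cells(sim_config(n_genes = n_genes, n_cells = n_cells,
                            seed = seed))
}
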