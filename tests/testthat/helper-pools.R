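# shared builders for small synthetic datasets used across test files

small_design <- function(n_strains = 60L, seed = 1L, generations = 5,
                         chip_sd = 0.2, noise_sd = 0.3, tag_offset = 0.5) {
  pool_design(n_strains = n_strains, n_controls = 12L, n_reps_per_dose = 3L,
              generations = generations, chip_sd = chip_sd,
              noise_sd = noise_sd, tag_offset = tag_offset, seed = seed)
}

# complete-null gene matrices on the 12/3/3/3 layout (one generation)
null_gene_matrices <- function(n_genes, chip_sd = 0.2, noise_sd = 0.3,
                               seed = 1L, delta = 0.5) {
  dose <- rep(c("control", "25", "50", "100"), c(12L, 3L, 3L, 3L))
  withr::with_seed(seed, {
    chip_eff <- matrix(rnorm(n_genes * 21L, 0, chip_sd), n_genes)
    up <- 10 + chip_eff + matrix(rnorm(n_genes * 21L, 0, noise_sd), n_genes)
    down <- 10 + delta + chip_eff +
      matrix(rnorm(n_genes * 21L, 0, noise_sd), n_genes)
    list(up = up, down = down, dose = dose)
  })
}

# a path graph pathway over the given node ids
path_pathway <- function(nodes, id = "pw") {
  list(id = id, nodes = nodes,
       edges = cbind(nodes[-length(nodes)], nodes[-1L]))
}
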