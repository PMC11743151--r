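# shared in-code fixtures; everything is generated, nothing is stored

make_index <- function(lst, species = "homo_sapiens") {
  structure(lapply(lst, toupper), species = species, class = "target_index")
}

make_zscores <- function(z, populations = NULL, coords = NULL) {
  structure(
    list(z = z, mean = rowMeans(z), sd = rep(1, nrow(z)),
         coords = coords, populations = populations),
    class = "mir_zscores"
  )
}

make_counts <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  mir_counts(m, ...)
}

# standard planted comparative dataset at the default study conditions:
# delta = 2, 20 targets per miRNA, 200 cells per population
planted_dataset <- function(seed, n_mirnas = 10, n_cells = 400,
                            n_genes = 500, delta = 2, disjoint = FALSE) {
  idx <- build_target_index(filter_mtis(generate_mti_fixture(
    n_mirnas = n_mirnas, targets_per_mirna = 20, n_genes = n_genes,
    seed = 42, disjoint = disjoint
  )))
  sim <- generate_single_cell_dataset(
    idx, planted_mirnas = names(idx)[1], n_genes = n_genes,
    n_cells = n_cells, delta = delta, seed = seed
  )
  list(index = idx, sim = sim)
}

all_binary_lists <- function(N) {
  grid <- as.matrix(expand.grid(rep(list(0:1), N)))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
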