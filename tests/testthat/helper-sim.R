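# small simulated studies shared across tests

two_cond <- function(g = 0.2, n_rep = 3) {
  tibble::tibble(
    genotype = "wt", timepoint = c("T0", "T1W"),
    global_factor = c(1, g), n_replicates = n_rep,
    batch = "B1", relative_cells = 1
  )
}

small_sim <- function(seed = 1, g = 0.2, n_genes = 300, depth = 5e4,
                      phi = 0.05, de_fraction = 0, ...) {
  simulate_counts(sim_config(
    n_genes = n_genes, conditions = two_cond(g),
    nb_dispersion = phi, depth_per_sample = depth,
    de_fraction = de_fraction, seed = seed, ...
  ))
}

# counts table built directly from a matrix of spike rows + gene rows
toy_counts <- function(spike_mat, gene_mat = NULL) {
  rownames(spike_mat) <- paste0("spk", seq_len(nrow(spike_mat)))
  m <- spike_mat
  if (!is.null(gene_mat)) {
    rownames(gene_mat) <- paste0("g", seq_len(nrow(gene_mat)))
    m <- rbind(gene_mat, spike_mat)
  }
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  as_count_tbl(m, spike_features = rownames(spike_mat))
}
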