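# Shared fixtures: a scaled-down simulation design for fast tests, and small
# hand-built count matrices.

# Scaled-down design for fast tests. The gene count must stay well above
# the 399-feature QC threshold so clean cells are not excluded wholesale.
small_design <- function(seed = 1L, ...) {
  simulation_design(
    cells_per_sample = 120,
    n_genes = 1000,
    markers_per_population = 15,
    n_gradient_genes = 80,
    seed = seed,
    ...
  )
}

tiny_counts <- function() {
  m <- matrix(c(1, 0,
                0, 2,
                5, 5), nrow = 3, byrow = TRUE)
  count_matrix(m, gene_ids = c("g1", "mt-Nd1", "Hbb-bs"),
               cell_ids = c("c1", "c2"))
}

# deterministic random sparse integer matrix
random_counts <- function(n_genes = 100, n_cells = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_genes * n_cells, 20, 0.1), n_genes, n_cells)
  count_matrix(m, gene_ids = sprintf("g%03d", seq_len(n_genes)),
               cell_ids = sprintf("c%03d", seq_len(n_cells)))
}

# a hand-assembled pseudo-bulk container for direct DE testing
make_pb <- function(y, conditions = rep(c("control", "cKO"), each = 4),
                    cluster = 1L) {
  if (is.null(rownames(y))) rownames(y) <- sprintf("g%04d", seq_len(nrow(y)))
  structure(list(
    counts = y,
    samples = tibble::tibble(sample_id = paste0("s", seq_len(ncol(y))),
                             cluster = cluster, condition = conditions,
                             n_cells = 100L),
    analyzable_clusters = unique(cluster)
  ), class = "waterfall_pseudobulk")
}

# two well-separated Gaussian blobs as a genes x cells matrix
blob_matrix <- function(n1 = 60, n2 = 40, dim = 10, sep = 20, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(n1 * dim), nrow = dim),
             matrix(rnorm(n2 * dim, mean = sep), nrow = dim))
  rownames(x) <- sprintf("g%02d", seq_len(dim))
  colnames(x) <- sprintf("c%03d", seq_len(n1 + n2))
  x
}
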