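child_seed <- function(seed, stage) {
  # stage-indexed child seeds so stages can be rerun independently
  (as.integer(seed) + 1009L * as.integer(stage)) %% .Machine$integer.max
}

write_stage_tsv <- function(df, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  p <- file.path(outdir, paste0(name, ".tsv"))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' Run the full analysis pipeline
#'
#' Orchestrates merge, cell QC, gene filtering, pool-based normalization,
#' mean-variance decomposition with denoised PCA, t-SNE, Ward clustering
#' with a dynamic tree cut, marker discovery, optional pseudo-bulk
#' Fisher-exact annotation, SOM/MST condition enrichment, differential 2D
#' density maps, and cluster-stratified pseudo-bulk differential expression
#' with competitive gene-set testing. Every stochastic stage receives a
#' child seed derived from the configured seed, so the run is deterministic;
#' a manifest records the configuration, the seed, per-stage cell/gene
#' counts and the hashes of every written output.
#'
#' @param samples Either the path of a sample-sheet TSV (columns
#'   `sample_id`, `path`, `condition`) or a pre-merged list with `counts`,
#'   `cells`, `genes` (e.g. from [simulate_waterfall()]).
#' @param config An [analysis_config()].
#' @param outdir Output directory for stage TSVs (or `NULL` for none).
#' @param reference Optional reference for annotation: a list with `binary`
#'   (logical genes x types matrix), e.g. [simulate_reference()].
#' @param gene_sets Optional named list of gene-symbol sets for the
#'   competitive gene-set test (see [read_gmt()]).
#' @param run_tsne Compute the t-SNE embedding (default TRUE).
#' @return A list of class `waterfall_run` with the stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(samples, config = analysis_config(), outdir = NULL,
                         reference = NULL, gene_sets = NULL,
                         run_tsne = TRUE) {
  t0 <- Sys.time()
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), seed = config$rng_seed,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## -- merge ---------------------------------------------------------------
  if (is.character(samples)) {
    sheet <- read_sample_sheet(samples)
    loaded <- lapply(seq_len(nrow(sheet)), function(i) {
      x <- read_10x_mtx(sheet$path[i], config = config)
      cells <- cell_table(colnames(x$counts), sheet$sample_id[i],
                          sheet$condition[i])
      list(counts = x$counts, cells = cells, genes = x$genes)
    })
    genes <- loaded[[1]]$genes
    merged <- merge_samples(loaded)
    counts <- merged$counts
    cells <- merged$cells
  } else {
    counts <- samples$counts
    cells <- samples$cells
    genes <- samples$genes
  }
  stopifnot(identical(cells$cell_id, colnames(counts)))
  note("merge", n_samples = length(unique(cells$sample_id)),
       n_genes = nrow(counts), n_cells = ncol(counts))
  conditions <- unique(cells$condition)
  two_conditions <- length(conditions) == 2

  ## -- cell QC -------------------------------------------------------------
  metrics <- compute_qc_metrics(counts, genes)
  qc <- cell_qc_mask(metrics, config)
  write_stage_tsv(qc, outdir, "qc_cells")
  counts <- counts[, qc$keep, drop = FALSE]
  cells <- cells[qc$keep, , drop = FALSE]
  note("cell_qc", n_kept = sum(qc$keep), n_excluded = sum(!qc$keep))

  ## -- gene filter ---------------------------------------------------------
  gene_keep <- gene_abundance_filter(counts, config)
  counts <- counts[gene_keep, , drop = FALSE]
  genes_kept <- genes[gene_keep, , drop = FALSE]
  note("gene_filter", n_kept = sum(gene_keep), n_removed = sum(!gene_keep))

  ## -- normalization -------------------------------------------------------
  sf <- pool_size_factors(counts, pool_sizes = config$pool_sizes)
  logcounts <- lognormalize(counts, sf)
  write_stage_tsv(tibble::tibble(cell_id = names(sf), size_factor = sf),
                  outdir, "size_factors")
  note("normalize", mean_factor = mean(sf))

  ## -- variance / dimred ---------------------------------------------------
  trend <- fit_mean_variance_trend(logcounts, span = config$loess_span)
  decomp <- decompose_variance(logcounts, trend)
  write_stage_tsv(decomp, outdir, "variance_decomposition")
  hvg <- select_hvg(decomp, n = config$n_hvg)
  log_hvg <- logcounts[hvg, , drop = FALSE]
  pca_hvg <- denoised_pca(log_hvg, decomp)
  pca_full <- denoised_pca(logcounts, decomp,
                           max_rank = max(50, config$n_som_pcs))
  note("dimred", n_hvg = length(hvg), d_hvg = pca_hvg$d, d_full = pca_full$d)
  write_stage_tsv(tibble::tibble(cell_id = rownames(pca_hvg$scores),
                                 as.data.frame(pca_hvg$scores)),
                  outdir, "pca_scores")
  tsne <- NULL
  if (run_tsne && nrow(pca_hvg$scores) >= 3 * config$tsne_perplexity + 2) {
    tsne <- tsne_embed(pca_hvg$scores, perplexity = config$tsne_perplexity,
                       seed = child_seed(config$rng_seed, 1))
    write_stage_tsv(tsne, outdir, "tsne")
  }

  ## -- clustering ----------------------------------------------------------
  tree <- ward_cluster(log_hvg)
  clusters <- dynamic_cut(tree, log_hvg,
                          min_cluster_size = config$min_cluster_size)
  labels <- clusters$labels
  write_stage_tsv(tidy(clusters), outdir, "clusters")
  note("cluster", K = clusters$K)
  markers <- NULL
  if (clusters$K >= 2) {
    markers <- find_markers(log_hvg, labels,
                            top_n = config$top_markers_per_pair)
    write_stage_tsv(markers$table, outdir, "markers")
  }

  ## -- annotation ----------------------------------------------------------
  annotation <- NULL
  if (!is.null(reference)) {
    ref_cond <- if ("control" %in% conditions) "control" else conditions[1]
    pb_ann <- pseudobulk_by_cluster(counts, labels, cells,
                                    condition_filter = ref_cond)
    log_cpm <- log2(sweep(pb_ann, 2, colSums(pb_ann), "/") * 1e6 + 1)
    bin <- binarize_expression(log_cpm)
    annotation <- fisher_annotation(bin$expressed, reference$binary,
                                    fdr = config$fdr_threshold)
    write_stage_tsv(annotation$all, outdir, "annotation")
    note("annotate", threshold = bin$threshold,
         n_reported = nrow(annotation$report))
  }

  ## -- topology / density --------------------------------------------------
  n_pcs <- min(config$n_som_pcs, ncol(pca_full$scores))
  som <- NULL
  if (nrow(pca_full$scores) >= prod(config$som_grid)) {
    som <- train_som(pca_full$scores[, seq_len(n_pcs), drop = FALSE],
                     grid = config$som_grid,
                     seed = child_seed(config$rng_seed, 2))
    write_stage_tsv(som$mst_edges, outdir, "som_mst")
  }
  enrichment <- NULL
  density <- NULL
  if (two_conditions) {
    if (!is.null(som)) {
      enrichment <- node_condition_enrichment(som$assignment, cells)
      write_stage_tsv(enrichment, outdir, "som_enrichment")
    }
    density <- condition_density_maps(pca_hvg$scores[, 1:2], cells,
                                      prior = config$density_prior)
    if (!is.null(outdir)) {
      write_density_tsv(density$diff, file.path(outdir, "diff_density.tsv"))
    }
  } else {
    message("single condition '", conditions,
            "': density and DE stages skipped")
    note("skipped", reason = "single condition",
         stages = c("density", "de", "gsea"))
  }

  ## -- pseudo-bulk DE / GSEA -----------------------------------------------
  de <- NULL
  gsea <- NULL
  pb <- NULL
  if (two_conditions) {
    pb <- aggregate_pseudobulk(counts, labels, cells,
                               min_cells = config$min_cells_aggregate)
    note("aggregate", n_aggregates = ncol(pb$counts),
         analyzable = pb$analyzable_clusters)
    if (length(pb$analyzable_clusters)) {
      analyzed_cells <- labels %in% pb$analyzable_clusters
      detection <- Matrix::rowSums(counts[, analyzed_cells, drop = FALSE] > 0)
      de_list <- list()
      gsea_list <- list()
      for (k in pb$analyzable_clusters) {
        mask <- filter_de_genes(
          pb$counts[, pb$samples$cluster == k, drop = FALSE], detection,
          min_cpm = config$de_min_cpm, min_samples = config$de_min_samples,
          min_cells = config$de_min_cells_detected)
        dek <- nbglm_de(pb, k, gene_mask = mask, fdr = config$fdr_threshold)
        de_list[[as.character(k)]] <- dek
        if (!is.null(gene_sets)) {
          z <- de_zscores(dek)
          names(z) <- genes_kept$symbol[match(names(z), genes_kept$gene_id)]
          gk <- camera_test(z, gene_sets, rho = config$camera_rho,
                            min_set_size = config$min_set_size)
          if (nrow(gk)) gk$cluster <- k
          gsea_list[[as.character(k)]] <- gk
        }
      }
      de <- dplyr::bind_rows(lapply(de_list, tibble::as_tibble))
      write_stage_tsv(de, outdir, "de")
      if (!is.null(gene_sets)) {
        gsea <- dplyr::bind_rows(gsea_list)
        write_stage_tsv(gsea, outdir, "gsea")
      }
      note("de", n_clusters_tested = length(pb$analyzable_clusters),
           n_de = sum(de$de, na.rm = TRUE))
    }
  }

  ## -- manifest ------------------------------------------------------------
  if (!is.null(outdir)) {
    files <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$hashes <- as.list(tools::md5sum(files))
    names(manifest$hashes) <- basename(files)
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(outdir)) {
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }

  structure(list(
    counts = counts, cells = cells, genes = genes_kept,
    qc = qc, size_factors = sf, logcounts = logcounts,
    decomposition = decomp, hvg = hvg, pca = pca_hvg, pca_full = pca_full,
    tsne = tsne, clusters = clusters, markers = markers,
    annotation = annotation, som = som, enrichment = enrichment,
    density = density, pseudobulk = pb, de = de, gsea = gsea,
    manifest = manifest
  ), class = "waterfall_run")
}

#' @export
print.waterfall_run <- function(x, ...) {
  cat("<waterfall_run>\n")
  cat("  cells kept:", ncol(x$counts), " genes kept:", nrow(x$counts), "\n")
  cat("  clusters:", x$clusters$K, "\n")
  if (!is.null(x$pseudobulk)) {
    cat("  pseudo-bulk aggregates:", ncol(x$pseudobulk$counts), "\n")
  }
  if (!is.null(x$de)) cat("  DE genes (q<0.05):", sum(x$de$de), "\n")
  invisible(x)
}

#' Write a density map as TSV with axis headers
#' @param map A `waterfall_density`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(map, path) {
  z <- map$z
  dimnames(z) <- list(format(map$x, digits = 10), format(map$y, digits = 10))
  write.table(z, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
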