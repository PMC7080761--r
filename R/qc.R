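#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the total UMI count (library size), the number
#' of detected genes, the fraction of UMIs attributed to mitochondrial genes
#' and the number of UMIs attributed to hemoglobin genes. A cell with zero
#' counts has `mito_fraction = 0` by definition.
#'
#' @param counts Genes x cells count matrix.
#' @param genes A [gene_table()] with `is_mito` / `is_hemoglobin` flags
#'   matching the rows of `counts`.
#' @return A tibble with columns `cell_id`, `libsize`, `n_features`,
#'   `mito_fraction`, `hemoglobin_umis`.
#' @export
compute_qc_metrics <- function(counts, genes) {
  stopifnot(nrow(genes) == nrow(counts),
            all(genes$gene_id == rownames(counts)))
  libsize <- Matrix::colSums(counts)
  n_features <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[genes$is_mito, , drop = FALSE])
  hb <- Matrix::colSums(counts[genes$is_hemoglobin, , drop = FALSE])
  tibble::tibble(
    cell_id = colnames(counts),
    libsize = as.numeric(libsize),
    n_features = as.integer(n_features),
    mito_fraction = ifelse(libsize > 0, mito / libsize, 0),
    hemoglobin_umis = as.integer(hb)
  )
}

#' Cell quality-control decisions
#'
#' A cell is kept iff `log10(libsize) >= min_log10_libsize` (default 2.8,
#' i.e. at least 631 UMIs), `log10(n_features) >= min_log10_features`
#' (default 2.6, i.e. at least 399 detected genes), its mitochondrial UMI
#' fraction is at most `max_mito_fraction` (default 5%, exactly 5% is kept)
#' and it has no more than `max_hemoglobin_umis` hemoglobin UMIs (default 0:
#' any hemoglobin read excludes the cell). Every excluded cell gets at least
#' one exclusion reason.
#'
#' @param metrics Output of [compute_qc_metrics()].
#' @param config An [analysis_config()].
#' @return The metrics tibble with logical columns `keep`, `low_libsize`,
#'   `low_features`, `high_mito`, `hemoglobin` and a `reasons` string.
#' @export
cell_qc_mask <- function(metrics, config = analysis_config()) {
  low_lib <- log10(pmax(metrics$libsize, 1e-300)) < config$min_log10_libsize
  low_feat <- log10(pmax(metrics$n_features, 1e-300)) < config$min_log10_features
  high_mito <- metrics$mito_fraction > config$max_mito_fraction
  hb <- metrics$hemoglobin_umis > config$max_hemoglobin_umis
  reasons <- character(nrow(metrics))
  tags <- cbind(low_libsize = low_lib, low_features = low_feat,
                high_mito = high_mito, hemoglobin = hb)
  reasons <- apply(tags, 1, function(r) paste(colnames(tags)[r], collapse = ";"))
  dplyr::mutate(metrics,
                low_libsize = low_lib,
                low_features = low_feat,
                high_mito = high_mito,
                hemoglobin = hb,
                keep = !(low_lib | low_feat | high_mito | hb),
                reasons = reasons)
}

#' Low-abundance gene filter
#'
#' A gene is kept when the log2 of its average CPM over cells is at least
#' `min_avg_log2_cpm` (default 0.005), with `CPM = count / libsize * 1e6`.
#' Cell QC must be applied first: cells with zero library size are an error.
#'
#' @param counts Genes x cells count matrix of QC-passing cells.
#' @param config An [analysis_config()].
#' @return A named logical vector over genes (`TRUE` = keep).
#' @export
gene_abundance_filter <- function(counts, config = analysis_config()) {
  libsize <- Matrix::colSums(counts)
  if (any(libsize == 0)) {
    stop("cells with zero library size present; apply cell QC first")
  }
  cpm <- methods::as(counts %*% Matrix::Diagonal(x = 1e6 / libsize), "CsparseMatrix")
  avg <- Matrix::rowMeans(cpm)
  keep <- log2(avg) >= config$min_avg_log2_cpm
  keep[avg == 0] <- FALSE
  stats::setNames(as.logical(keep), rownames(counts))
}
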