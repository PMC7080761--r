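#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline into one validated object.
#' The defaults are the fixed, bimodality-derived values used throughout the
#' analysis: cells are kept when `log10(libsize) >= 2.8` and
#' `log10(n_features) >= 2.6`, with at most 5% mitochondrial UMIs and zero
#' hemoglobin UMIs; genes are kept when their average log2 CPM is at least
#' 0.005; the mean-variance trend uses a loess span of 0.05; t-SNE uses
#' perplexity 30 on the top 500 most variable genes; the SOM uses the first
#' 30 denoised principal components on a 9x9 grid; pseudo-bulk aggregates
#' require at least 20 cells and genes enter the DE fit with CPM > 1 in at
#' least 3 aggregates and detection in at least 20 cells; significance is
#' called at 5% FDR; the competitive gene-set test uses an inter-gene
#' correlation of 0.01 on sets of more than ten genes; differential densities
#' add a prior of 1e-3 before taking the log2 ratio.
#'
#' @param min_log10_libsize Minimum log10 total UMIs per cell (inclusive).
#' @param min_log10_features Minimum log10 detected genes per cell (inclusive).
#' @param max_mito_fraction Maximum tolerated mitochondrial UMI fraction
#'   (inclusive: exactly this fraction is kept).
#' @param max_hemoglobin_umis Maximum tolerated hemoglobin UMIs per cell.
#' @param min_avg_log2_cpm Minimum average log2 CPM for a gene to be kept.
#' @param loess_span Span of the loess mean-variance trend.
#' @param n_hvg Number of highly variable genes for embedding/clustering.
#' @param tsne_perplexity t-SNE perplexity.
#' @param n_som_pcs Number of leading principal components fed to the SOM.
#' @param som_grid Integer vector of length 2, SOM grid dimensions.
#' @param min_cells_aggregate Minimum cells per (sample, cluster) aggregate.
#' @param de_min_cpm CPM threshold for the DE gene filter (strictly greater).
#' @param de_min_samples Number of aggregates that must exceed `de_min_cpm`.
#' @param de_min_cells_detected Minimum single cells a DE gene is detected in.
#' @param fdr_threshold Benjamini-Hochberg FDR threshold.
#' @param camera_rho Assumed inter-gene correlation within gene sets.
#' @param min_set_size Smallest tested gene-set size (sets of fewer genes are
#'   skipped; the default 11 tests sets of more than ten genes).
#' @param density_prior Prior added to densities before the log2 ratio.
#' @param top_markers_per_pair Markers taken per pairwise cluster comparison.
#' @param pool_sizes Pool sizes for deconvolution size factors.
#' @param min_cluster_size Minimum cluster size for the dynamic tree cut.
#' @param hemoglobin_prefixes Symbol prefixes flagged as hemoglobin genes.
#' @param mito_prefix Symbol prefix (case-insensitive) flagged as mitochondrial.
#' @param rng_seed Integer seed fanned out to the stochastic stages.
#'
#' @return An object of class `waterfall_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$min_log10_libsize
#' @export
analysis_config <- function(min_log10_libsize = 2.8,
                            min_log10_features = 2.6,
                            max_mito_fraction = 0.05,
                            max_hemoglobin_umis = 0,
                            min_avg_log2_cpm = 0.005,
                            loess_span = 0.05,
                            n_hvg = 500,
                            tsne_perplexity = 30,
                            n_som_pcs = 30,
                            som_grid = c(9L, 9L),
                            min_cells_aggregate = 20,
                            de_min_cpm = 1,
                            de_min_samples = 3,
                            de_min_cells_detected = 20,
                            fdr_threshold = 0.05,
                            camera_rho = 0.01,
                            min_set_size = 11,
                            density_prior = 1e-3,
                            top_markers_per_pair = 10,
                            pool_sizes = c(21, 41, 61, 81, 101),
                            min_cluster_size = 20,
                            hemoglobin_prefixes = c("Hba", "Hbb"),
                            mito_prefix = "mt-",
                            rng_seed = 1L) {
  cfg <- list(
    min_log10_libsize = min_log10_libsize,
    min_log10_features = min_log10_features,
    max_mito_fraction = max_mito_fraction,
    max_hemoglobin_umis = max_hemoglobin_umis,
    min_avg_log2_cpm = min_avg_log2_cpm,
    loess_span = loess_span,
    n_hvg = as.integer(n_hvg),
    tsne_perplexity = tsne_perplexity,
    n_som_pcs = as.integer(n_som_pcs),
    som_grid = as.integer(som_grid),
    min_cells_aggregate = as.integer(min_cells_aggregate),
    de_min_cpm = de_min_cpm,
    de_min_samples = as.integer(de_min_samples),
    de_min_cells_detected = as.integer(de_min_cells_detected),
    fdr_threshold = fdr_threshold,
    camera_rho = camera_rho,
    min_set_size = as.integer(min_set_size),
    density_prior = density_prior,
    top_markers_per_pair = as.integer(top_markers_per_pair),
    pool_sizes = as.numeric(pool_sizes),
    min_cluster_size = as.integer(min_cluster_size),
    hemoglobin_prefixes = as.character(hemoglobin_prefixes),
    mito_prefix = mito_prefix,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "waterfall_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_log10_libsize > 0,
    cfg$min_log10_features > 0,
    cfg$max_mito_fraction >= 0, cfg$max_mito_fraction <= 1,
    cfg$max_hemoglobin_umis >= 0,
    cfg$loess_span > 0, cfg$loess_span <= 1,
    cfg$n_hvg >= 1,
    cfg$tsne_perplexity > 0,
    length(cfg$som_grid) == 2, all(cfg$som_grid >= 1),
    cfg$min_cells_aggregate >= 1,
    cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
    cfg$camera_rho >= 0, cfg$camera_rho < 1,
    cfg$min_set_size >= 1,
    cfg$density_prior > 0,
    all(cfg$pool_sizes >= 1),
    cfg$min_cluster_size >= 1
  )
  invisible(cfg)
}

#' @export
print.waterfall_config <- function(x, ...) {
  cat("<waterfall_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' Serialization round-trips exactly: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A `waterfall_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `waterfall_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "waterfall_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}
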