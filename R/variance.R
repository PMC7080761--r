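#' Fit the mean-variance trend of log-expression
#'
#' Fits a locally weighted (loess, degree 1, tricube weights) regression of
#' the per-gene variance on the per-gene mean of log-expression. The small
#' default span of 0.05 follows the sparse-data setting; for small gene sets
#' a larger span is appropriate. The returned function evaluates the fitted
#' technical variance at arbitrary means, clamping queries outside the fitted
#' mean range to the nearest fitted point and clamping negative fits to zero.
#'
#' @param logcounts Genes x cells log-expression matrix.
#' @param span Loess span in (0, 1].
#' @return A function `f(mean) -> variance`, with attributes `means` and
#'   `variances` (the per-gene statistics the trend was fitted to).
#' @export
fit_mean_variance_trend <- function(logcounts, span = analysis_config()$loess_span) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (nrow(logcounts) < 10) stop("need at least 10 genes to fit a trend")
  mu <- rowMeans(logcounts)
  v <- apply(logcounts, 1, stats::var)
  # guarantee enough local points for a degree-1 fit at the stated span
  eff_span <- max(span, 4 / length(mu))
  fit <- suppressWarnings(stats::loess(
    v ~ mu, span = eff_span, degree = 1, family = "gaussian",
    surface = "direct",
    control = stats::loess.control(iterations = 1)
  ))
  rng <- range(mu)
  f <- function(m) {
    m <- pmin(pmax(m, rng[1]), rng[2])
    pmax(as.numeric(stats::predict(fit, data.frame(mu = m))), 0)
  }
  attr(f, "means") <- mu
  attr(f, "variances") <- v
  f
}

#' Decompose gene variance into technical and biological components
#'
#' The technical component of a gene is the trend value at its mean; the
#' biological component is the residual (total minus technical) and may be
#' negative. The decomposition conserves the total variance exactly.
#'
#' @param logcounts Genes x cells log-expression matrix.
#' @param trend A trend function from [fit_mean_variance_trend()].
#' @return A tibble with columns `gene_id`, `mean`, `total`, `technical`,
#'   `biological`.
#' @export
decompose_variance <- function(logcounts, trend) {
  mu <- rowMeans(logcounts)
  total <- apply(logcounts, 1, stats::var)
  technical <- trend(mu)
  tibble::tibble(
    gene_id = rownames(logcounts),
    mean = mu,
    total = total,
    technical = technical,
    biological = total - technical
  )
}

#' Select highly variable genes
#'
#' Top `n` genes by biological variance component; ties are broken by
#' lexicographic gene id so the selection is deterministic.
#'
#' @param decomposition Output of [decompose_variance()].
#' @param n Number of genes (default 500).
#' @return Character vector of gene ids.
#' @export
select_hvg <- function(decomposition, n = analysis_config()$n_hvg) {
  ord <- order(-decomposition$biological, decomposition$gene_id)
  utils::head(decomposition$gene_id[ord], n)
}

#' Denoised principal component analysis
#'
#' PCA on the centered log-expression (cells as observations), retaining the
#' smallest number `d` of leading components such that the total variance of
#' the discarded components does not exceed the summed technical variance of
#' the genes in the matrix: the discarded subspace is then attributable to
#' technical noise. A floor of `d >= 2` is enforced.
#'
#' @param logcounts Genes x cells log-expression matrix (possibly restricted
#'   to highly variable genes).
#' @param decomposition Output of [decompose_variance()] covering the genes
#'   of `logcounts`.
#' @param max_rank Largest number of components to compute.
#' @return A list of class `waterfall_pca` with `scores` (cells x d),
#'   `component_variances` (length d, non-increasing), `d`, `total_variance`
#'   and `technical_sum`.
#' @export
denoised_pca <- function(logcounts, decomposition, max_rank = 50) {
  if (ncol(logcounts) < 3) stop("need at least 3 cells for PCA")
  tech <- decomposition$technical[match(rownames(logcounts),
                                        decomposition$gene_id)]
  if (anyNA(tech)) stop("decomposition does not cover all genes")
  x <- t(logcounts)                       # cells x genes
  x <- sweep(x, 2, colMeans(x), "-")
  n <- nrow(x)
  kmax <- min(max_rank, n - 1L, ncol(x))
  if (kmax >= min(n, ncol(x)) - 1L || min(dim(x)) <= 60) {
    sv <- svd(x, nu = kmax, nv = 0)
    dvals <- sv$d[seq_len(kmax)]
    scores <- sv$u %*% diag(dvals, kmax)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(571L)   # fixed internal seed: truncated SVD is reproducible
    sv <- irlba::irlba(x, nv = kmax)
    dvals <- sv$d
    scores <- x %*% sv$v
  }
  # canonical signs: the largest-magnitude score of each component positive
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  compvar <- dvals^2 / (n - 1)
  total <- sum(apply(logcounts, 1, stats::var))
  tech_sum <- sum(pmax(tech, 0))
  discarded <- total - cumsum(compvar)
  ok <- which(discarded <= tech_sum + 1e-12)
  d <- if (length(ok)) min(ok) else kmax
  d <- max(2L, min(d, kmax))
  rownames(scores) <- colnames(logcounts)
  structure(list(
    scores = scores[, seq_len(d), drop = FALSE],
    component_variances = compvar[seq_len(d)],
    d = d,
    all_component_variances = compvar,
    total_variance = total,
    technical_sum = tech_sum
  ), class = "waterfall_pca")
}

#' @export
print.waterfall_pca <- function(x, ...) {
  cat("<waterfall_pca> ", nrow(x$scores), " cells, d = ", x$d,
      " retained components\n", sep = "")
  invisible(x)
}

#' t-SNE embedding
#'
#' Two-dimensional Barnes-Hut t-SNE of the denoised PC scores, delegated to
#' the Rtsne implementation; deterministic given the seed.
#'
#' @param scores Cells x components matrix (e.g. `waterfall_pca$scores`).
#' @param perplexity t-SNE perplexity (default 30). At least
#'   `3 * perplexity` cells are required.
#' @param seed Integer seed.
#' @return A tibble with columns `cell_id`, `tsne1`, `tsne2`.
#' @export
tsne_embed <- function(scores, perplexity = analysis_config()$tsne_perplexity,
                       seed = 1L) {
  if (perplexity <= 0) stop("perplexity must be positive")
  n <- nrow(scores)
  if (n < 3 * perplexity + 2) {
    stop("too few cells (", n, ") for perplexity ", perplexity)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fit <- Rtsne::Rtsne(as.matrix(scores), dims = 2, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  tibble::tibble(
    cell_id = rownames(scores) %||% as.character(seq_len(n)),
    tsne1 = fit$Y[, 1],
    tsne2 = fit$Y[, 2]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
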