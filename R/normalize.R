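#' Pool-based deconvolution size factors
#'
#' Estimates per-cell size factors by summing cells into overlapping pools
#' (which avoids the dominance of zeros in sparse UMI data), normalizing each
#' pooled profile against an average pseudo-cell, and deconvolving the pooled
#' estimates back to per-cell factors by least squares. The computation is
#' delegated to the pooled deconvolution estimator of the scran package; the
#' returned factors are rescaled to unit mean.
#'
#' @param counts Genes x cells count matrix (QC-passing cells).
#' @param pool_sizes Pool sizes; capped at the number of available cells.
#' @param clusters Optional per-cell grouping for within-cluster pooling
#'   (factors are then rescaled to be comparable across clusters).
#' @return A named numeric vector of positive size factors with mean 1.
#' @export
pool_size_factors <- function(counts, pool_sizes = analysis_config()$pool_sizes,
                              clusters = NULL) {
  n <- ncol(counts)
  sizes <- unique(pmin(pool_sizes, if (is.null(clusters)) n else
    min(table(clusters))))
  sf <- scran::calculateSumFactors(methods::as(counts, "CsparseMatrix"),
                                   sizes = sizes, clusters = clusters,
                                   min.mean = 0.1, positive = FALSE)
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("non-positive deconvolution size factors; use larger pools or ",
         "filter low-coverage cells first")
  }
  sf <- sf / mean(sf)
  stats::setNames(sf, colnames(counts))
}

#' Library-size factors
#'
#' Per-cell total counts rescaled to unit mean; the no-pooling baseline the
#' deconvolution estimator is compared against.
#'
#' @param counts Genes x cells count matrix.
#' @return A named numeric vector with mean 1.
#' @export
libsize_factors <- function(counts) {
  ls <- Matrix::colSums(counts)
  if (any(ls == 0)) stop("cells with zero library size")
  stats::setNames(as.numeric(ls / mean(ls)), colnames(counts))
}

#' Log-normalized expression
#'
#' `value = log2(count / size_factor + 1)`: monotone in the count for a fixed
#' factor, zero at zero, and invariant to a common rescaling of counts and
#' factors.
#'
#' @param counts Genes x cells count matrix.
#' @param size_factors Positive per-cell factors (named or positional).
#' @return A dense genes x cells matrix of log2 expression values.
#' @export
lognormalize <- function(counts, size_factors) {
  stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  if (!is.null(names(size_factors))) {
    stopifnot(identical(names(size_factors), colnames(counts)))
  }
  m <- as.matrix(counts %*% Matrix::Diagonal(x = 1 / size_factors))
  dimnames(m) <- dimnames(counts)
  log2(m + 1)
}
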