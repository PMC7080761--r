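#' Per-cluster pseudo-bulk profiles of control cells
#'
#' Sums the raw UMI counts of the cells of one condition (default: control)
#' within each cluster, creating one pseudo-bulk profile per cluster. Column
#' sums are conserved exactly: each profile equals the gene-wise sum of its
#' member cells. Clusters without any cell of the requested condition are
#' omitted with a warning.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Per-cell cluster labels aligned to columns.
#' @param cells A [cell_table()] (used for the condition filter); pass `NULL`
#'   to aggregate all cells.
#' @param condition_filter Condition whose cells are aggregated.
#' @return A genes x clusters matrix; column names are the cluster labels.
#' @export
pseudobulk_by_cluster <- function(counts, labels, cells = NULL,
                                  condition_filter = "control") {
  keep <- rep(TRUE, ncol(counts))
  if (!is.null(cells)) {
    stopifnot(identical(cells$cell_id, colnames(counts)))
    keep <- cells$condition == condition_filter
  }
  labs <- sort(unique(as.integer(labels)))
  out <- matrix(0, nrow = nrow(counts), ncol = length(labs),
                dimnames = list(rownames(counts), as.character(labs)))
  empty <- character(0)
  for (j in seq_along(labs)) {
    idx <- which(labels == labs[j] & keep)
    if (!length(idx)) {
      empty <- c(empty, as.character(labs[j]))
      next
    }
    out[, j] <- Matrix::rowSums(counts[, idx, drop = FALSE])
  }
  if (length(empty)) {
    warning("cluster(s) without ", condition_filter, " cells omitted: ",
            paste(empty, collapse = ", "))
    out <- out[, setdiff(colnames(out), empty), drop = FALSE]
  }
  out
}

#' Classify genes as expressed / not-expressed per profile
#'
#' Pools the nonzero log2(CPM+1) values of all profiles, fits a two-component
#' Gaussian mixture to the clearly bimodal pooled distribution, and places
#' the threshold at the point of equal posterior probability between the two
#' components. A gene is expressed in a profile when its value exceeds the
#' threshold; all-zero genes are never expressed. When the mixture fit is
#' degenerate (components indistinguishable or the fit fails) the pooled
#' median of nonzero values is used instead, with a warning.
#'
#' @param log_profiles Genes x profiles matrix of log2(CPM+1) values.
#' @return A list with `expressed` (logical matrix like `log_profiles`) and
#'   `threshold` (scalar, on the same log2 scale).
#' @export
binarize_expression <- function(log_profiles) {
  vals <- log_profiles[log_profiles > 0]
  if (!length(vals)) stop("no nonzero expression values")
  threshold <- mixture_threshold(vals)
  if (is.na(threshold)) {
    warning("degenerate mixture fit; falling back to the pooled median")
    threshold <- stats::median(vals)
  }
  expressed <- log_profiles > threshold
  expressed[log_profiles == 0] <- FALSE
  list(expressed = expressed, threshold = threshold)
}

# Equal-posterior point of a two-component univariate Gaussian mixture,
# NA when the fit is degenerate (BIC prefers a single component, i.e. the
# pooled distribution is not bimodal).
mixture_threshold <- function(vals) {
  # deterministic initialization subset (mclust subsamples randomly above
  # 2000 points): evenly spaced order statistics cover the distribution
  sub <- order(vals)[unique(round(seq(1, length(vals),
                                      length.out = min(2000, length(vals)))))]
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(vals, G = 1:2, modelNames = "V",
                                    initialization = list(subset = sub),
                                    verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit) || is.null(fit$parameters)) return(NA_real_)
  if (fit$G < 2) return(NA_real_)
  m <- fit$parameters$mean
  s <- sqrt(fit$parameters$variance$sigmasq)
  if (length(s) == 1) s <- rep(s, 2)
  w <- fit$parameters$pro
  o <- order(m)
  m <- m[o]; s <- s[o]; w <- w[o]
  if (!all(is.finite(c(m, s, w))) || any(s <= 0)) return(NA_real_)
  # solve w1 N(x; m1, s1) = w2 N(x; m2, s2) between the means
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, m[1], s[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, m[2], s[2], log = TRUE)
  }
  if (f(m[1]) * f(m[2]) > 0) return(NA_real_)
  stats::uniroot(f, c(m[1], m[2]))$root
}

#' Fisher-exact reference annotation of pseudo-bulk profiles
#'
#' For every (cluster, reference) pair, the overlap of expressed genes over
#' the shared gene universe is laid out as a 2x2 table (expressed in both /
#' query only / reference only / neither) and tested for enrichment with a
#' one-sided Fisher exact test (the hypergeometric upper tail). P-values are
#' BH-adjusted across references within each cluster; per cluster, up to
#' `top_n` significant references are reported, sorted by decreasing odds
#' ratio (infinite odds ratios first, ties by p-value).
#'
#' @param query_binary Logical genes x clusters matrix (from
#'   [binarize_expression()]).
#' @param reference_binary Logical genes x references matrix.
#' @param fdr BH threshold for reporting (default 0.05).
#' @param top_n Maximum reported references per cluster (default 10).
#' @return A list with `report` (tibble of the reported entries) and `all`
#'   (tibble of every tested pair with columns `cluster`, `reference`,
#'   `overlap`, `odds_ratio`, `p`, `q`).
#' @export
fisher_annotation <- function(query_binary, reference_binary, fdr = 0.05,
                              top_n = 10) {
  shared <- intersect(rownames(query_binary), rownames(reference_binary))
  if (!length(shared)) stop("empty shared gene universe")
  q <- query_binary[shared, , drop = FALSE]
  r <- reference_binary[shared, , drop = FALSE]
  rows <- list()
  for (ci in colnames(q)) {
    qs <- q[, ci]
    res <- lapply(colnames(r), function(ri) {
      rs <- r[, ri]
      a <- sum(qs & rs); b <- sum(qs & !rs)
      cc <- sum(!qs & rs); d <- sum(!qs & !rs)
      p <- stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
      or <- if (b * cc == 0) {
        if (a * d == 0) NaN else Inf
      } else (a * d) / (b * cc)
      tibble::tibble(cluster = ci, reference = ri, overlap = a,
                     odds_ratio = or, p = p)
    })
    tab <- dplyr::bind_rows(res)
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    rows[[ci]] <- tab
  }
  all_tab <- dplyr::bind_rows(rows)
  report <- all_tab |>
    dplyr::filter(.data$q <= fdr) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(is.infinite(.data$odds_ratio)),
                   dplyr::desc(.data$odds_ratio), .data$p,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
  list(report = report, all = all_tab)
}
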