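#' Ward hierarchical clustering of cells
#'
#' Agglomerative clustering on the Euclidean distances between cells with
#' Ward's criterion (minimal within-cluster variance increase; the squared
#' distance implementation, so two singletons merge at their Euclidean
#' distance). Deterministic for a given input.
#'
#' @param logcounts Genes x cells log-expression matrix (typically restricted
#'   to highly variable genes).
#' @return An `hclust` tree over cells.
#' @export
ward_cluster <- function(logcounts) {
  if (ncol(logcounts) < 2) stop("need at least 2 cells")
  if (!all(is.finite(logcounts))) stop("non-finite values in log-expression")
  # Euclidean distances via the Gram matrix (BLAS) rather than stats::dist:
  # identical result, much faster for thousands of cells
  g <- crossprod(logcounts)
  n2 <- diag(g)
  d2 <- outer(n2, n2, "+") - 2 * g
  d <- sqrt(pmax(d2, 0))
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

node_members <- function(merge, node) {
  # leaves under internal node `node` (1-based row of merge)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    for (child in merge[nd, ]) {
      if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
    }
  }
  out
}

#' Dynamic tree cut
#'
#' Adaptive dendrogram cutting: starting from the root, a branch is split
#' into its two children when the merge-height gap at its top (branch height
#' minus the height of its tallest child) stands out against the spread of
#' the merge heights inside the branch (`gap > gap_factor * sd(internal
#' heights)`), recursively. Resulting clusters smaller than
#' `min_cluster_size` are dissolved and their cells assigned to the nearest
#' retained cluster centroid in the clustering space.
#'
#' @param tree An `hclust` object from [ward_cluster()].
#' @param logcounts The matrix the tree was built from (used for centroid
#'   rescue of leftover cells).
#' @param min_cluster_size Minimum cluster size (default 20).
#' @param gap_factor Multiplier on the internal height spread that a gap
#'   must exceed for a split (default 3).
#' @return A list of class `waterfall_clusters` with `labels` (named integer
#'   vector, contiguous 1..K), `K`, `tree` and `rescued` (ids of cells
#'   assigned by centroid rescue).
#' @export
dynamic_cut <- function(tree, logcounts,
                       min_cluster_size = analysis_config()$min_cluster_size,
                       gap_factor = 3) {
  n <- length(tree$order)
  if (min_cluster_size > n) stop("min_cluster_size exceeds the number of cells")
  merge <- tree$merge
  height <- tree$height
  nmerge <- nrow(merge)

  # subtree statistics per internal node: size, sum/sumsq of internal heights
  size <- integer(nmerge)
  hsum <- numeric(nmerge)
  hsumsq <- numeric(nmerge)
  hcount <- integer(nmerge)
  topheight <- numeric(nmerge)
  for (i in seq_len(nmerge)) {
    s <- 0L; hs <- 0; hq <- 0; hc <- 0L
    for (child in merge[i, ]) {
      if (child < 0) {
        s <- s + 1L
      } else {
        s <- s + size[child]
        hs <- hs + hsum[child] + height[child]
        hq <- hq + hsumsq[child] + height[child]^2
        hc <- hc + hcount[child] + 1L
      }
    }
    size[i] <- s; hsum[i] <- hs; hsumsq[i] <- hq; hcount[i] <- hc
    topheight[i] <- height[i]
  }
  internal_sd <- function(i) {
    if (hcount[i] < 2) return(0)
    m <- hsum[i] / hcount[i]
    v <- (hsumsq[i] - hcount[i] * m^2) / (hcount[i] - 1)
    sqrt(max(v, 0))
  }
  child_height <- function(child) if (child < 0) 0 else height[child]

  clusters <- list()
  splitrec <- function(node) {
    if (node < 0) {
      clusters[[length(clusters) + 1L]] <<- -node
      return(invisible())
    }
    left <- merge[node, 1]; right <- merge[node, 2]
    gap <- height[node] - max(child_height(left), child_height(right))
    if (size[node] >= 2 * min_cluster_size && hcount[node] >= 2 &&
        gap > gap_factor * internal_sd(node)) {
      splitrec(left)
      splitrec(right)
    } else {
      clusters[[length(clusters) + 1L]] <<- node_members(merge, node)
    }
  }
  splitrec(nmerge)

  sizes <- lengths(clusters)
  keep <- sizes >= min_cluster_size
  if (!any(keep)) {
    # nothing survives the size rule: a single cluster
    labels <- rep(1L, n)
    names(labels) <- tree$labels %||% as.character(seq_len(n))
    return(structure(list(labels = labels, K = 1L, tree = tree,
                          rescued = character(0)),
                     class = "waterfall_clusters"))
  }
  retained <- clusters[keep]
  # deterministic numbering: by decreasing size, ties by smallest member
  ord <- order(-lengths(retained),
               vapply(retained, min, numeric(1)))
  retained <- retained[ord]
  labels <- integer(n)
  for (k in seq_along(retained)) labels[retained[[k]]] <- k

  leftovers <- unlist(clusters[!keep], use.names = FALSE)
  rescued <- character(0)
  if (length(leftovers)) {
    x <- t(logcounts)
    cent <- vapply(retained, function(ii) colMeans(x[ii, , drop = FALSE]),
                   numeric(ncol(x)))
    for (i in leftovers) {
      dd <- colSums((cent - x[i, ])^2)
      labels[i] <- which.min(dd)
    }
    rescued <- (tree$labels %||% as.character(seq_len(n)))[leftovers]
  }
  names(labels) <- tree$labels %||% as.character(seq_len(n))
  structure(list(labels = labels, K = length(retained), tree = tree,
                 rescued = rescued),
            class = "waterfall_clusters")
}

#' @export
print.waterfall_clusters <- function(x, ...) {
  cat("<waterfall_clusters> K =", x$K, "\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
glance.waterfall_clusters <- function(x, ...) {
  tibble::tibble(K = x$K, n_cells = length(x$labels),
                 n_rescued = length(x$rescued),
                 min_size = min(table(x$labels)),
                 max_size = max(table(x$labels)))
}

#' @export
tidy.waterfall_clusters <- function(x, ...) {
  tibble::tibble(cell_id = names(x$labels), cluster = as.integer(x$labels))
}

row_group_stats <- function(logcounts, idx) {
  x <- logcounts[, idx, drop = FALSE]
  n <- length(idx)
  m <- rowMeans(x)
  v <- if (n > 1) (rowSums(x^2) - n * m^2) / (n - 1) else rep(NA_real_, nrow(x))
  list(n = n, mean = m, var = pmax(v, 0))
}

#' Cluster marker genes by pairwise comparison
#'
#' For every ordered pair of clusters, each gene is compared between the two
#' groups on log-expression with a Welch two-sample statistic; within a focal
#' cluster, genes are ranked by p-value among those with a positive log
#' fold-change (upregulated in the focal cluster). The top-set of a cluster
#' is the union of the top `top_n` genes from each of its pairwise
#' comparisons; the global top-set unions these across clusters, which is the
#' gene list used for marker heatmaps.
#'
#' @param logcounts Genes x cells log-expression matrix.
#' @param labels Per-cell cluster labels (vector aligned to columns).
#' @param top_n Markers per pairwise comparison (default 10).
#' @return A list of class `waterfall_markers`: `table` (tibble with columns
#'   `cluster`, `versus`, `gene_id`, `lfc`, `statistic`, `p`, `rank`),
#'   `top_sets` (list per cluster) and `top_set` (global union).
#' @export
find_markers <- function(logcounts, labels,
                         top_n = analysis_config()$top_markers_per_pair) {
  labs <- sort(unique(as.integer(labels)))
  if (length(labs) < 2) stop("need at least 2 clusters")
  stats_by <- lapply(labs, function(k) row_group_stats(logcounts,
                                                       which(labels == k)))
  names(stats_by) <- as.character(labs)
  rows <- list()
  for (a in labs) {
    sa <- stats_by[[as.character(a)]]
    for (b in setdiff(labs, a)) {
      sb <- stats_by[[as.character(b)]]
      if (sa$n < 2 || sb$n < 2) {
        warning("cluster pair (", a, ", ", b, ") skipped: a cluster of size 1")
        next
      }
      se2 <- sa$var / sa$n + sb$var / sb$n
      tstat <- (sa$mean - sb$mean) / sqrt(pmax(se2, 1e-300))
      df <- se2^2 / pmax((sa$var / sa$n)^2 / (sa$n - 1) +
                           (sb$var / sb$n)^2 / (sb$n - 1), 1e-300)
      df[se2 == 0] <- 1
      p <- 2 * stats::pt(-abs(tstat), df)
      p[se2 == 0 & sa$mean == sb$mean] <- 1
      lfc <- sa$mean - sb$mean
      ord <- order(p, -lfc, rownames(logcounts))
      rnk <- integer(length(p)); rnk[ord] <- seq_along(ord)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cluster = a, versus = b, gene_id = rownames(logcounts),
        lfc = lfc, statistic = tstat, p = p, rank = rnk
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (!nrow(tab)) {
    return(structure(list(table = tab, top_sets = list(), top_set = character(0)),
                     class = "waterfall_markers"))
  }
  up <- dplyr::filter(tab, .data$lfc > 0)
  top_sets <- lapply(labs, function(k) {
    sub <- dplyr::filter(up, .data$cluster == k)
    ids <- unlist(lapply(split(sub, sub$versus), function(d) {
      d$gene_id[order(d$p, -d$lfc, d$gene_id)][seq_len(min(top_n, nrow(d)))]
    }), use.names = FALSE)
    sort(unique(ids))
  })
  names(top_sets) <- as.character(labs)
  structure(list(table = tab, top_sets = top_sets,
                 top_set = sort(unique(unlist(top_sets, use.names = FALSE)))),
            class = "waterfall_markers")
}

#' @export
print.waterfall_markers <- function(x, ...) {
  cat("<waterfall_markers>", length(unique(x$table$cluster)), "clusters,",
      length(x$top_set), "genes in the global top-set\n")
  invisible(x)
}

#' @export
tidy.waterfall_markers <- function(x, ...) x$table
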