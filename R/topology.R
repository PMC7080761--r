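#' Train a batch self-organizing map
#'
#' Batch SOM on a rectangular grid (default 9x9) with a Gaussian
#' neighborhood whose radius shrinks linearly from half the larger grid
#' dimension to 1 over the epochs; the Gaussian width is a third of the
#' current radius, so the final epochs are essentially winner-only updates
#' and the codebook converges onto the data. The codebook is initialized
#' from a seeded random sample of data rows, making training fully
#' deterministic given the seed. Input is typically the cells x 30 matrix of
#' leading denoised principal components.
#'
#' @param x Cells x features matrix (e.g. `pca$scores[, 1:30]`).
#' @param grid Integer vector of length 2 (default `c(9, 9)`).
#' @param seed Integer seed for codebook initialization.
#' @param epochs Number of batch epochs (default 10).
#' @return A list of class `waterfall_som` with `codebook` (nodes x
#'   features), `grid`, `grid_coords` (nodes x 2), `assignment` (per-cell
#'   best matching node) and `mst_edges` (tibble `from`, `to`, `weight`).
#' @export
train_som <- function(x, grid = analysis_config()$som_grid, seed = 1L,
                      epochs = 10) {
  x <- as.matrix(x)
  n_nodes <- prod(grid)
  if (nrow(x) < n_nodes) {
    stop("fewer cells (", nrow(x), ") than SOM nodes (", n_nodes,
         "); use a smaller grid")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  gx <- rep(seq_len(grid[1]), times = grid[2])
  gy <- rep(seq_len(grid[2]), each = grid[1])
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2

  codebook <- x[sample.int(nrow(x), n_nodes), , drop = FALSE]
  r0 <- max(grid) / 2
  n_tune <- max(2L, epochs %/% 5)           # final winner-only epochs
  n_decay <- max(epochs - n_tune, 1L)
  for (e in seq_len(epochs)) {
    bmu <- nearest_node(x, codebook)
    if (e <= n_decay) {
      radius <- r0 + (1 - r0) * (e - 1) / max(n_decay - 1, 1)
      sigma <- radius / 4
      h <- exp(-grid_d2 / (2 * sigma^2))    # nodes x nodes
      w <- h[bmu, , drop = FALSE]           # cells x nodes
      denom <- colSums(w)
      num <- crossprod(w, x)                # nodes x features
      upd <- denom > 0
      codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    } else {
      # winner-only refinement with empty-node repair: an unoccupied node is
      # relocated onto the currently worst-quantized observation
      for (k in seq_len(n_nodes)) {
        sel <- bmu == k
        if (any(sel)) codebook[k, ] <- colMeans(x[sel, , drop = FALSE])
      }
      empty <- setdiff(seq_len(n_nodes), unique(bmu))
      if (length(empty)) {
        qerr <- rowSums((x - codebook[bmu, , drop = FALSE])^2)
        worst <- order(qerr, decreasing = TRUE)
        worst <- worst[!duplicated(bmu[worst])]
        nrep <- min(length(worst), length(empty))
        if (nrep > 0) {
          codebook[empty[seq_len(nrep)], ] <- x[worst[seq_len(nrep)], ,
                                                drop = FALSE]
        }
      }
    }
  }
  bmu <- nearest_node(x, codebook)
  rownames(codebook) <- sprintf("node%02d", seq_len(n_nodes))
  structure(list(
    codebook = codebook,
    grid = grid,
    grid_coords = cbind(gx = gx, gy = gy),
    assignment = stats::setNames(bmu, rownames(x)),
    mst_edges = som_mst(codebook)
  ), class = "waterfall_som")
}

nearest_node <- function(x, codebook) {
  # squared distances via the expansion ||x||^2 - 2 x.c + ||c||^2
  cross <- x %*% t(codebook)
  c2 <- rowSums(codebook^2)
  d2 <- sweep(-2 * cross, 2, c2, "+")       # row-constant ||x||^2 dropped
  max.col(-d2, ties.method = "first")
}

#' @export
print.waterfall_som <- function(x, ...) {
  cat("<waterfall_som>", paste(x$grid, collapse = "x"), "grid,",
      length(x$assignment), "cells assigned\n")
  invisible(x)
}

#' @export
glance.waterfall_som <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$codebook),
                 n_cells = length(x$assignment),
                 n_occupied = length(unique(x$assignment)),
                 n_mst_edges = nrow(x$mst_edges))
}

#' Minimal spanning tree of a SOM codebook
#'
#' Kruskal's algorithm on the Euclidean distances between codebook vectors,
#' with deterministic index tie-breaking; the result spans all nodes with
#' `nodes - 1` edges (zero-weight edges between duplicate nodes allowed).
#'
#' @param codebook Nodes x features matrix.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
som_mst <- function(codebook) {
  n <- nrow(codebook)
  if (n < 2) return(tibble::tibble(from = integer(0), to = integer(0),
                                   weight = numeric(0)))
  d <- as.matrix(stats::dist(codebook))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[ij], ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  # union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  from <- integer(n - 1); to <- integer(n - 1); wt <- numeric(n - 1)
  k <- 0L
  for (e in seq_len(nrow(ij))) {
    a <- find(ij[e, 1]); b <- find(ij[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      from[k] <- ij[e, 1]; to[k] <- ij[e, 2]
      wt[k] <- d[ij[e, 1], ij[e, 2]]
      if (k == n - 1L) break
    }
  }
  tibble::tibble(from = from, to = to, weight = wt)
}

#' Per-node condition enrichment
#'
#' For every occupied SOM node, counts control and cKO cells and computes the
#' normalized cKO share `(n_cko / N_cko) / (n_cko / N_cko + n_ctrl /
#' N_ctrl)`, where `N_*` are the condition totals: normalizing by the totals
#' keeps unequal condition sizes from biasing every node toward the larger
#' condition. The share is 0.5 for a node mirroring the global composition
#' and 1 for an all-cKO node.
#'
#' @param assignment Per-cell node assignment (named by cell id), e.g.
#'   `som$assignment`.
#' @param cells A [cell_table()] covering the assigned cells.
#' @return A tibble with columns `node`, `n_control`, `n_cko`, `cko_share`.
#' @export
node_condition_enrichment <- function(assignment, cells) {
  idx <- match(names(assignment), cells$cell_id)
  if (anyNA(idx)) stop("cells table does not cover all assigned cells")
  cond <- cells$condition[idx]
  n_ctrl_tot <- sum(cond == "control")
  n_cko_tot <- sum(cond == "cKO")
  tab <- tibble::tibble(node = as.integer(assignment), condition = cond) |>
    dplyr::count(.data$node, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  if (!"control" %in% names(tab)) tab$control <- 0L
  if (!"cKO" %in% names(tab)) tab$cKO <- 0L
  rate_ctrl <- if (n_ctrl_tot > 0) tab$control / n_ctrl_tot else 0
  rate_cko <- if (n_cko_tot > 0) tab$cKO / n_cko_tot else 0
  denom <- rate_ctrl + rate_cko
  tibble::tibble(
    node = tab$node,
    n_control = tab$control,
    n_cko = tab$cKO,
    cko_share = ifelse(denom > 0, rate_cko / denom, NA_real_)
  ) |> dplyr::arrange(.data$node)
}

#' Two-dimensional kernel density estimate
#'
#' Product-Gaussian KDE on a regular grid. The per-axis bandwidth is the
#' normal-reference rule `1.06 * min(sd, IQR / 1.34) * n^(-1/5)` and the
#' grid spans the data range extended by 5% on each side. The density is
#' nonnegative and integrates to 1 (up to the mass smoothed past the grid
#' margins, negligible at the sample sizes used here).
#'
#' @param points A two-column matrix (or data frame) of coordinates.
#' @param grid Integer vector of length 2, grid resolution (default 100x100).
#' @param limits Optional list of two length-2 ranges overriding the grid
#'   span (used to place two conditions on a shared grid).
#' @return A list of class `waterfall_density` with `x`, `y` (axis
#'   coordinates) and `z` (density matrix, `length(x)` x `length(y)`).
#' @export
kde2d_density <- function(points, grid = c(100, 100), limits = NULL) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2)
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points")
  bw <- vapply(1:2, function(j) {
    s <- stats::sd(pts[, j])
    iq <- stats::IQR(pts[, j]) / 1.34
    spread <- if (iq > 0) min(s, iq) else s
    1.06 * spread * n^(-1 / 5)
  }, numeric(1))
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    stop("zero spread on an axis; cannot estimate a 2D density")
  }
  if (is.null(limits)) {
    limits <- lapply(1:2, function(j) {
      r <- range(pts[, j])
      pad <- 0.05 * diff(r)
      c(r[1] - pad, r[2] + pad)
    })
  }
  gx <- seq(limits[[1]][1], limits[[1]][2], length.out = grid[1])
  gy <- seq(limits[[2]][1], limits[[2]][2], length.out = grid[2])
  kx <- outer(gx, pts[, 1], function(g, p) stats::dnorm(g - p, sd = bw[1]))
  ky <- outer(gy, pts[, 2], function(g, p) stats::dnorm(g - p, sd = bw[2]))
  z <- (kx %*% t(ky)) / n
  structure(list(x = gx, y = gy, z = z, bandwidth = bw, n = n),
            class = "waterfall_density")
}

#' @export
print.waterfall_density <- function(x, ...) {
  cat("<waterfall_density>", length(x$x), "x", length(x$y),
      "grid from", x$n, "points\n")
  invisible(x)
}

#' Differential 2D density
#'
#' The log2 ratio of the cKO density over the control density after adding a
#' prior count (default 1e-3) to both estimates. Exactly antisymmetric under
#' swapping the conditions and identically zero for identical inputs. Both
#' maps must live on the same grid; use the `limits` argument of
#' [kde2d_density()] to compute them on the shared range of both conditions.
#'
#' @param map_cko,map_ctrl `waterfall_density` maps on identical grids.
#' @param prior Prior count added to both densities (default 1e-3).
#' @return A `waterfall_density`-like object whose `z` holds the log2 ratio.
#' @export
differential_density <- function(map_cko, map_ctrl,
                                 prior = analysis_config()$density_prior) {
  if (!isTRUE(all.equal(map_cko$x, map_ctrl$x)) ||
      !isTRUE(all.equal(map_cko$y, map_ctrl$y))) {
    stop("density grids differ; compute both maps on shared limits")
  }
  # as a difference of logs the swap is bitwise antisymmetric
  z <- log2(map_cko$z + prior) - log2(map_ctrl$z + prior)
  structure(list(x = map_cko$x, y = map_cko$y, z = z, prior = prior),
            class = c("waterfall_diff_density", "waterfall_density"))
}

#' Shared-grid condition densities over two embedding axes
#'
#' Convenience wrapper: computes the per-condition densities of a 2D
#' embedding (e.g. PC1/PC2) on the union range of both conditions, plus
#' their differential map.
#'
#' @param coords Cells x 2 matrix.
#' @param cells A [cell_table()] aligned to the rows of `coords`.
#' @param grid Grid resolution.
#' @param prior Prior count for the log ratio.
#' @return A list with `control`, `cko` and `diff` maps.
#' @export
condition_density_maps <- function(coords, cells, grid = c(100, 100),
                                   prior = analysis_config()$density_prior) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(cells))
  limits <- lapply(1:2, function(j) {
    r <- range(coords[, j])
    pad <- 0.05 * diff(r)
    c(r[1] - pad, r[2] + pad)
  })
  ctrl <- kde2d_density(coords[cells$condition == "control", , drop = FALSE],
                        grid = grid, limits = limits)
  cko <- kde2d_density(coords[cells$condition == "cKO", , drop = FALSE],
                       grid = grid, limits = limits)
  list(control = ctrl, cko = cko,
       diff = differential_density(cko, ctrl, prior = prior))
}
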