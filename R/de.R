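#' Aggregate single cells into pseudo-bulk samples
#'
#' Sums the UMI counts of the cells of each sample within each cluster,
#' keeping an aggregate only when at least `min_cells` cells contribute.
#' Total counts of the contributing cells are conserved exactly. A cluster is
#' analyzable for differential expression only when at least
#' `min_replicates` aggregates per condition remain.
#'
#' @param counts Genes x cells count matrix (QC-passing cells).
#' @param labels Per-cell cluster labels aligned to columns.
#' @param cells A [cell_table()] aligned to columns.
#' @param min_cells Minimum cells per (sample, cluster) aggregate
#'   (default 20).
#' @param min_replicates Minimum aggregates per condition for a cluster to
#'   be analyzable (default 3).
#' @return A list of class `waterfall_pseudobulk` with `counts` (genes x
#'   aggregates), `samples` (tibble: `sample_id`, `cluster`, `condition`,
#'   `n_cells`) and `analyzable_clusters`.
#' @export
aggregate_pseudobulk <- function(counts, labels, cells,
                                 min_cells = analysis_config()$min_cells_aggregate,
                                 min_replicates = 3) {
  stopifnot(identical(cells$cell_id, colnames(counts)),
            length(labels) == ncol(counts))
  groups <- split(seq_len(ncol(counts)),
                  list(sample = cells$sample_id, cluster = labels),
                  drop = TRUE)
  keep <- groups[lengths(groups) >= min_cells]
  if (!length(keep)) {
    warning("no (sample, cluster) aggregate reaches ", min_cells, " cells")
    return(structure(list(
      counts = matrix(0, nrow(counts), 0, dimnames = list(rownames(counts), NULL)),
      samples = tibble::tibble(sample_id = character(0), cluster = integer(0),
                               condition = character(0), n_cells = integer(0)),
      analyzable_clusters = integer(0)
    ), class = "waterfall_pseudobulk"))
  }
  pb <- vapply(keep, function(idx) {
    as.numeric(Matrix::rowSums(counts[, idx, drop = FALSE]))
  }, numeric(nrow(counts)))
  rownames(pb) <- rownames(counts)
  meta <- do.call(rbind, strsplit(names(keep), ".", fixed = TRUE))
  samples <- tibble::tibble(
    sample_id = meta[, 1],
    cluster = as.integer(meta[, 2]),
    condition = cells$condition[match(meta[, 1], cells$sample_id)],
    n_cells = as.integer(lengths(keep))
  )
  colnames(pb) <- paste(samples$sample_id, samples$cluster, sep = ".")
  reps <- samples |>
    dplyr::count(.data$cluster, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  for (cc in c("control", "cKO")) if (!cc %in% names(reps)) reps[[cc]] <- 0L
  analyzable <- reps$cluster[reps$control >= min_replicates &
                               reps$cKO >= min_replicates]
  structure(list(counts = pb, samples = samples,
                 analyzable_clusters = sort(analyzable)),
            class = "waterfall_pseudobulk")
}

#' @export
print.waterfall_pseudobulk <- function(x, ...) {
  cat("<waterfall_pseudobulk>", ncol(x$counts), "aggregates over",
      length(unique(x$samples$cluster)), "clusters;",
      length(x$analyzable_clusters), "analyzable\n")
  invisible(x)
}

#' DE gene filter for pseudo-bulk samples
#'
#' Keeps genes with CPM above `min_cpm` in at least `min_samples` aggregates
#' and detected (count > 0) in at least `min_cells` individual cells.
#'
#' @param pb_counts Genes x aggregates count matrix (one cluster's columns).
#' @param detection_counts Per-gene number of single cells the gene is
#'   detected in (computed on QC-passing cells of the analyzed clusters).
#' @param min_cpm,min_samples,min_cells Thresholds (defaults 1, 3, 20).
#' @return A named logical vector over genes.
#' @export
filter_de_genes <- function(pb_counts, detection_counts,
                            min_cpm = analysis_config()$de_min_cpm,
                            min_samples = analysis_config()$de_min_samples,
                            min_cells = analysis_config()$de_min_cells_detected) {
  stopifnot(length(detection_counts) == nrow(pb_counts))
  libsize <- colSums(pb_counts)
  cpm <- sweep(pb_counts, 2, libsize, "/") * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples & detection_counts >= min_cells
  stats::setNames(as.logical(keep), rownames(pb_counts))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization. The reference
#' column is the library whose upper-quartile count fraction is closest to
#' the mean upper quartile; per column, M (log2 count-fraction ratio vs the
#' reference) and A (average log2 abundance) are computed over genes with
#' positive counts in both libraries, the M values are trimmed 30% two-sided
#' and the A values 5% two-sided, and the factor is 2 to the
#' inverse-asymptotic-variance weighted mean of the retained M values.
#' Factors are rescaled to geometric mean 1, so uniform scaling of a column
#' leaves all factors at 1.
#'
#' @param pb_counts Genes x samples count matrix (at least two columns).
#' @return A named numeric vector of factors with geometric mean 1.
#' @export
tmm_factors <- function(pb_counts) {
  x <- as.matrix(pb_counts)
  if (ncol(x) < 2) stop("TMM needs at least 2 columns")
  N <- colSums(x)
  if (any(N == 0)) stop("column(s) with all-zero counts: ",
                        paste(which(N == 0), collapse = ", "))
  uq <- vapply(seq_len(ncol(x)), function(j) {
    stats::quantile(x[, j], 0.75, names = FALSE) / N[j]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(k) {
    if (k == ref) return(1)
    tmm_pair(x[, k], x[, ref], N[k], N[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(x))
}

tmm_pair <- function(obs, refc, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  pos <- obs > 0 & refc > 0
  obs <- obs[pos]; refc <- refc[pos]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (refc / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (refc / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - refc) / (n_ref * refc)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  fv <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  if (!is.finite(fv) || fv <= 0) 1 else fv
}

# Vectorized IRLS for an NB GLM with log link, per-sample offsets and a
# two-level condition design, fitted to every gene at once. Returns the
# coefficients, fitted means and per-gene log-likelihood (and the Cox-Reid
# adjustment term for the full design).
nbglm_fit <- function(y, offset, x = NULL, phi, max_iter = 50, tol = 1e-10) {
  G <- nrow(y); n <- ncol(y)
  off <- matrix(offset, G, n, byrow = TRUE)
  eff <- exp(offset)
  if (is.null(x)) {
    b0 <- log(pmax(rowSums(y), 0.25) / sum(eff))
    b1 <- NULL
  } else {
    s0 <- rowSums(y[, x == 0, drop = FALSE]); e0 <- sum(eff[x == 0])
    s1 <- rowSums(y[, x == 1, drop = FALSE]); e1 <- sum(eff[x == 1])
    b0 <- log(pmax(s0, 0.25) / e0)
    b1 <- log(pmax(s1, 0.25) / e1) - b0
  }
  cr <- rep(0, G)
  for (it in seq_len(max_iter)) {
    eta <- off + b0 + if (is.null(x)) 0 else outer(b1, x)
    eta <- pmin(eta, 40)
    mu <- pmax(exp(eta), 1e-8)   # floor keeps separated groups finite
    w <- mu / (1 + phi * mu)
    z <- (eta - off) + (y - mu) / mu
    wz <- w * z
    if (is.null(x)) {
      new0 <- rowSums(wz) / rowSums(w)
      new0 <- pmin(pmax(new0, -30), 30)
      delta <- abs(new0 - b0)
      b0 <- new0
      if (max(delta, na.rm = TRUE) < tol) break
    } else {
      s11 <- rowSums(w)
      sxx <- rowSums(w[, x == 1, drop = FALSE])
      sz <- rowSums(wz)
      sxz <- rowSums(wz[, x == 1, drop = FALSE])
      det <- s11 * sxx - sxx^2
      det <- pmax(det, 1e-300)
      new1 <- (s11 * sxz - sxx * sz) / det
      new0 <- (sz - sxx * new1) / s11
      # clamp both coefficients: for separated groups the MLE diverges in
      # (b0, b1) jointly while b0 + b1 stays finite
      new0 <- pmin(pmax(new0, -30), 30)
      new1 <- pmin(pmax(new1, -30), 30)
      delta <- pmax(abs(new0 - b0), abs(new1 - b1))
      b0 <- new0; b1 <- new1
      if (max(delta, na.rm = TRUE) < tol) break
    }
  }
  eta <- off + b0 + if (is.null(x)) 0 else outer(b1, x)
  eta <- pmin(eta, 40)
  mu <- pmax(exp(eta), 1e-8)
  w <- mu / (1 + phi * mu)
  if (!is.null(x)) {
    s11 <- rowSums(w)
    sxx <- rowSums(w[, x == 1, drop = FALSE])
    cr <- 0.5 * log(pmax(s11 * sxx - sxx^2, 1e-300))
  } else {
    cr <- 0.5 * log(pmax(rowSums(w), 1e-300))
  }
  ll <- rowSums(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  list(b0 = b0, b1 = b1, mu = mu, ll = ll, cr = cr, iterations = it)
}

#' Estimate a common NB dispersion
#'
#' Maximizes the Cox-Reid adjusted profile likelihood of a single dispersion
#' shared by all genes, refitting the per-gene GLM coefficients at every
#' candidate value (1-D bounded search on the log scale). The adjustment
#' (half the log determinant of the weighted information) corrects the
#' downward bias of the raw profile maximum caused by estimating two
#' coefficients per gene from few replicates.
#'
#' @param y Genes x samples count matrix.
#' @param offset Per-sample log effective library sizes.
#' @param x Binary condition indicator per sample.
#' @param interval Search interval for the dispersion.
#' @return The estimated dispersion (scalar).
#' @export
estimate_common_dispersion <- function(y, offset, x,
                                       interval = c(1e-4, 4)) {
  apl <- function(log_phi) {
    fit <- nbglm_fit(y, offset, x, phi = exp(log_phi), max_iter = 30,
                     tol = 1e-8)
    sum(fit$ll - fit$cr)
  }
  opt <- stats::optimize(apl, log(interval), maximum = TRUE, tol = 1e-4)
  exp(opt$maximum)
}

#' Pseudo-bulk differential expression for one cluster
#'
#' Negative-binomial GLM per gene with log link, offsets equal to the log
#' effective library sizes (library size times TMM factor), and a design of
#' intercept plus condition. A common dispersion is estimated for the
#' cluster, per-gene coefficients are fitted by IRLS, and the condition
#' effect is tested by a likelihood-ratio test against the intercept-only
#' model with a chi-squared(1) reference. P-values are BH-adjusted within
#' the cluster and genes with `q < fdr` are flagged differentially
#' expressed.
#'
#' @param pb A `waterfall_pseudobulk` (see [aggregate_pseudobulk()]).
#' @param cluster Which cluster to test.
#' @param gene_mask Optional logical vector from [filter_de_genes()].
#' @param tmm Optional precomputed TMM factors for the cluster's columns.
#' @param fdr FDR threshold for the DE flag (default 0.05).
#' @param dispersion Optional fixed dispersion (skips estimation).
#' @return A tibble of class `waterfall_de` with columns `cluster`,
#'   `gene_id`, `log2fc` (cKO vs control), `lrt`, `p`, `q`, `de`; the
#'   estimated `dispersion` and the design are kept as attributes.
#' @export
nbglm_de <- function(pb, cluster, gene_mask = NULL, tmm = NULL,
                     fdr = analysis_config()$fdr_threshold,
                     dispersion = NULL) {
  sel <- pb$samples$cluster == cluster
  if (!any(sel)) stop("no aggregates for cluster ", cluster)
  cond <- pb$samples$condition[sel]
  if (sum(cond == "control") < 3 || sum(cond == "cKO") < 3) {
    stop("cluster ", cluster, " has fewer than 3 replicates per condition")
  }
  y <- pb$counts[, sel, drop = FALSE]
  if (!is.null(gene_mask)) y <- y[gene_mask, , drop = FALSE]
  y <- y[rowSums(y) > 0, , drop = FALSE]
  if (is.null(tmm)) tmm <- tmm_factors(y)
  offset <- log(colSums(y) * tmm)
  x <- as.numeric(cond == "cKO")
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(y, offset, x)
  }
  full <- nbglm_fit(y, offset, x, phi = dispersion)
  null <- nbglm_fit(y, offset, NULL, phi = dispersion)
  lrt <- pmax(2 * (full$ll - null$ll), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  res <- tibble::tibble(
    cluster = cluster,
    gene_id = rownames(y),
    log2fc = full$b1 / log(2),
    lrt = lrt,
    p = p,
    q = bh_fdr(p)
  )
  res$de <- res$q < fdr
  attr(res, "dispersion") <- dispersion
  attr(res, "n_samples") <- sum(sel)
  class(res) <- c("waterfall_de", class(res))
  res
}

#' @export
glance.waterfall_de <- function(x, ...) {
  tibble::tibble(cluster = x$cluster[1],
                 n_genes = nrow(x),
                 n_de = sum(x$de, na.rm = TRUE),
                 dispersion = attr(x, "dispersion"),
                 n_samples = attr(x, "n_samples"))
}

#' @export
tidy.waterfall_de <- function(x, ...) tibble::as_tibble(x)

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in p), delegated to
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values (NA allowed).
#' @return Adjusted q-values of the same length.
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Competitive gene-set test with a variance inflation factor
#'
#' Tests whether the genes of a set have systematically larger or smaller
#' signed z-statistics than the remaining genes. For a set of `m` genes out
#' of `G` tested, the statistic is the difference between the mean z inside
#' and outside the set; its null variance `(1/m + 1/(G-m)) * sigma^2 * VIF`
#' is inflated by `VIF = 1 + (m-1) * rho` to account for an assumed
#' inter-gene correlation `rho` (default 0.01) within sets, with `sigma^2`
#' estimated empirically from all tested z-statistics. The two-sided p-value
#' uses the normal approximation; with `rho = 0` the procedure reduces to an
#' unadjusted two-sample z-test. Only sets with at least `min_set_size`
#' genes after intersection with the tested genes are considered, and
#' p-values are BH-adjusted across the tested sets.
#'
#' @param gene_stats Named numeric vector of signed per-gene z-statistics
#'   (e.g. [de_zscores()] of a `waterfall_de` table).
#' @param sets Named list of gene identifier vectors (see [read_gmt()]).
#' @param rho Assumed inter-gene correlation (default 0.01).
#' @param min_set_size Smallest tested set size (default 11: sets of more
#'   than ten genes).
#' @return A tibble with columns `set`, `n_genes`, `direction` (Up/Down),
#'   `delta`, `p`, `q`.
#' @export
camera_test <- function(gene_stats, sets,
                        rho = analysis_config()$camera_rho,
                        min_set_size = analysis_config()$min_set_size) {
  z <- gene_stats[is.finite(gene_stats)]
  G <- length(z)
  if (G < 3) stop("too few gene statistics")
  sigma2 <- stats::var(z)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(z))
    m <- length(members)
    if (m < min_set_size || m >= G) return(NULL)
    inset <- names(z) %in% members
    delta <- mean(z[inset]) - mean(z[!inset])
    vif <- 1 + (m - 1) * rho
    vd <- (1 / m + 1 / (G - m)) * sigma2 * vif
    p <- 2 * stats::pnorm(-abs(delta) / sqrt(vd))
    tibble::tibble(set = nm, n_genes = m,
                   direction = ifelse(delta > 0, "Up", "Down"),
                   delta = delta, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$q <- bh_fdr(out$p) else out$q <- numeric(0)
  out
}

#' Signed z-statistics from a DE table
#'
#' The signed square root of the likelihood-ratio statistic, carrying the
#' sign of the log2 fold-change; the per-gene input to [camera_test()].
#'
#' @param de A `waterfall_de` tibble.
#' @return A named numeric vector (names are gene ids).
#' @export
de_zscores <- function(de) {
  stats::setNames(sign(de$log2fc) * sqrt(de$lrt), de$gene_id)
}
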