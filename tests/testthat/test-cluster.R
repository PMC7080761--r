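test_that("Ward linkage behaves on elementary configurations", {
  # two cells at (0,0) and (3,4) merge at their Euclidean distance 5
  x2 <- matrix(c(0, 0, 3, 4), 2, 2)
  dimnames(x2) <- list(c("g1", "g2"), c("a", "b"))
  tr <- ward_cluster(x2)
  expect_equal(tr$height, 5)

  # three collinear points 0, 1, 10: first merge joins the closest pair
  x3 <- matrix(c(0, 1, 10), 1, 3)
  dimnames(x3) <- list("g", c("p0", "p1", "p10"))
  tr3 <- ward_cluster(x3)
  expect_setequal(tr3$merge[1, ], c(-1, -2))

  # duplicate points merge at height zero
  xd <- matrix(c(1, 1, 5), 1, 3)
  dimnames(xd) <- list("g", c("a", "b", "c"))
  expect_equal(ward_cluster(xd)$height[1], 0)

  xbad <- matrix(c(1, NA, 2, 3), 2, 2)
  dimnames(xbad) <- list(c("g1", "g2"), c("a", "b"))
  expect_error(ward_cluster(xbad), "non-finite")
})

test_that("the dynamic cut separates blobs and keeps single blobs whole", {
  x <- blob_matrix(n1 = 200, n2 = 150, sep = 20, seed = 2)
  cl <- dynamic_cut(ward_cluster(x), x)
  expect_equal(cl$K, 2L)
  expect_equal(unname(table(cl$labels)), c(200L, 150L), ignore_attr = TRUE)

  for (s in 1:4) {
    set.seed(s)
    one <- matrix(rnorm(20 * 300), nrow = 20)
    dimnames(one) <- list(paste0("g", 1:20), paste0("c", 1:300))
    expect_equal(dynamic_cut(ward_cluster(one), one)$K, 1L)
  }

  expect_error(dynamic_cut(ward_cluster(x), x, min_cluster_size = 1000),
               "exceeds")
})

test_that("clustering recovers the planted populations on simulated data", {
  sim <- simulate_waterfall(small_design(seed = 7))
  qc <- cell_qc_mask(compute_qc_metrics(sim$counts, sim$genes))
  counts <- sim$counts[, qc$keep]
  cells <- sim$cells[qc$keep, ]
  lc <- lognormalize(counts, libsize_factors(counts))
  dec <- decompose_variance(lc, fit_mean_variance_trend(lc, span = 0.2))
  lch <- lc[select_hvg(dec, 200), ]
  cl <- dynamic_cut(ward_cluster(lch), lch)
  expect_gte(cl$K, 4L)
  expect_lte(cl$K, 6L)
  ari <- mclust::adjustedRandIndex(cl$labels, cells$truth_label)
  expect_gte(ari, 0.8)
})

test_that("cluster labels are equivariant under cell permutation", {
  x <- blob_matrix(n1 = 120, n2 = 60, sep = 15, seed = 4)
  cl <- dynamic_cut(ward_cluster(x), x)
  set.seed(9)
  perm <- sample(ncol(x))
  xp <- x[, perm]
  clp <- dynamic_cut(ward_cluster(xp), xp)
  # identical partitions: labels agree up to renaming
  expect_equal(mclust::adjustedRandIndex(cl$labels[perm], clp$labels), 1)
})

test_that("marker finding ranks exclusive genes first and is null-calibrated", {
  set.seed(5)
  n <- 60
  x <- matrix(rnorm(50 * n), 50, n)
  dimnames(x) <- list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:n))
  labels <- rep(c(1, 2), each = n / 2)
  x[1, labels == 1] <- x[1, labels == 1] + 10   # exclusive to cluster 1
  mk <- find_markers(x, labels)
  tab1 <- dplyr::filter(mk$table, cluster == 1, versus == 2)
  expect_equal(tab1$gene_id[tab1$rank == 1], "g01")
  expect_true("g01" %in% mk$top_sets[["1"]])

  # permuted labels: p-values approximately uniform
  set.seed(6)
  xnull <- matrix(rnorm(400 * n), 400, n)
  dimnames(xnull) <- list(sprintf("g%03d", 1:400), sprintf("c%02d", 1:n))
  mknull <- find_markers(xnull, sample(labels))
  ks <- stats::ks.test(dplyr::filter(mknull$table, cluster == 1)$p, "punif")
  expect_gt(ks$p.value, 0.01)

  w <- capture_warnings(find_markers(x, c(1, rep(2, n - 1))))
  expect_match(w, "size 1", all = FALSE)
})

test_that("planted population markers appear in their cluster's top-set", {
  sim <- simulate_waterfall(small_design(seed = 8))
  lc <- lognormalize(sim$counts, libsize_factors(sim$counts))
  labels <- as.integer(factor(sim$cells$truth_label,
                              levels = c("mono_early", "mono_late",
                                         "mac_early", "mac_inter",
                                         "mac_mature")))
  # program (on/off) genes produce the most extreme statistics, so the
  # planted graded markers are recovered with a slightly wider top-set
  mk <- find_markers(lc, labels, top_n = 50)
  mono_ids <- sim$genes$gene_id[sim$genes$symbol %in% c("Ccr2", "Ly6c2")]
  expect_true(all(mono_ids %in% mk$top_sets[["1"]]))
  mac_ids <- sim$genes$gene_id[sim$genes$symbol %in% c("Cx3cr1", "Adgre1")]
  expect_true(all(mac_ids %in% mk$top_sets[["5"]]))
})

test_that("pseudo-bulk profiles sum member cells exactly", {
  # two cells with counts (1, 2) and (3, 4): cluster sum (4, 6)
  m <- count_matrix(matrix(c(1, 2, 3, 4), 2, 2),
                    gene_ids = c("gA", "gB"), cell_ids = c("c1", "c2"))
  pb <- pseudobulk_by_cluster(m, c(1, 1))
  expect_equal(unname(pb[, 1]), c(4, 6))

  sim <- simulate_waterfall(small_design(seed = 2))
  labels <- as.integer(factor(sim$cells$truth_label))
  pb2 <- pseudobulk_by_cluster(sim$counts, labels, sim$cells, "control")
  ctrl <- sim$cells$condition == "control"
  expect_equal(sum(pb2), sum(sim$counts[, ctrl]))
  expect_lte(ncol(pb2), length(unique(labels)))

  cells_one <- cell_table(c("c1", "c2"), "s1", "cKO")
  expect_warning(pseudobulk_by_cluster(m, c(1, 1), cells_one, "control"),
                 "omitted")
})

test_that("binarization thresholds a bimodal mixture between its modes", {
  set.seed(3)
  low <- pmax(rnorm(4000, 0.5, 0.3), 0.01)
  high <- rnorm(4000, 6, 1)
  vals <- matrix(sample(c(low, high)), ncol = 4)
  rownames(vals) <- sprintf("g%04d", seq_len(nrow(vals)))
  b <- binarize_expression(vals)
  expect_gt(b$threshold, 0.5)
  expect_lt(b$threshold, 6)
  truth_high <- matrix(vals > 3, ncol = 4)
  expect_lt(mean((vals > b$threshold) != truth_high), 0.02)

  # all-zero genes are never expressed
  vz <- rbind(vals[1:50, ], matrix(0, 5, 4))
  rownames(vz) <- sprintf("g%02d", 1:55)
  bz <- binarize_expression(vz)
  expect_true(all(!bz$expressed[51:55, ]))

  # shifting all values shifts the threshold
  b2 <- binarize_expression(vals + 2)
  expect_equal(b2$threshold, b$threshold + 2, tolerance = 0.15)

  # unimodal input falls back to the pooled median with a warning
  set.seed(4)
  uni <- matrix(rnorm(2000, 5, 0.1), ncol = 2)
  rownames(uni) <- sprintf("g%04d", seq_len(nrow(uni)))
  expect_warning(bu <- binarize_expression(uni), "median")
  expect_equal(bu$threshold, median(uni[uni > 0]))
})

test_that("Fisher annotation matches enumeration and behaves on nulls", {
  # the worked 2x2 example [[25, 5], [15, 55]]
  qs <- c(rep(TRUE, 30), rep(FALSE, 70))
  rs <- c(rep(TRUE, 25), rep(FALSE, 5), rep(TRUE, 15), rep(FALSE, 55))
  qm <- matrix(qs, ncol = 1, dimnames = list(sprintf("g%03d", 1:100), "cl1"))
  rm_ <- matrix(rs, ncol = 1, dimnames = list(sprintf("g%03d", 1:100), "ref"))
  fa <- fisher_annotation(qm, rm_)
  enum <- sum(exp(lchoose(40, 25:30) + lchoose(60, 30 - (25:30)) -
                    lchoose(100, 30)))
  expect_equal(fa$all$p, enum, tolerance = 1e-12)
  expect_equal(fa$all$p, fisher.test(matrix(c(25, 5, 15, 55), 2),
                                     alternative = "greater")$p.value,
               tolerance = 1e-12)

  # a query identical to one reference ranks it first with the smallest p
  set.seed(7)
  ref3 <- matrix(runif(300 * 3) < 0.4, 300, 3,
                 dimnames = list(sprintf("g%03d", 1:300), c("A", "B", "C")))
  q1 <- matrix(ref3[, "B"], ncol = 1,
               dimnames = list(rownames(ref3), "cl1"))
  fa2 <- fisher_annotation(q1, ref3)
  expect_equal(fa2$report$reference[1], "B")
  expect_equal(min(fa2$all$p), fa2$all$p[fa2$all$reference == "B"])

  # independent random binaries: the enrichment test controls its size,
  # so significant calls at FDR 5% occur in at most ~5% of null tables
  # (binomial band: 5% + 3 sd at 1000 repetitions)
  sig <- vapply(1:1000, function(s) {
    set.seed(s)
    qq <- matrix(runif(1000) < 0.3, ncol = 1,
                 dimnames = list(sprintf("g%04d", 1:1000), "cl"))
    rr <- matrix(runif(1000) < 0.3, ncol = 1,
                 dimnames = list(sprintf("g%04d", 1:1000), "ref"))
    nrow(fisher_annotation(qq, rr)$report) > 0
  }, logical(1))
  expect_lte(mean(sig), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))

  expect_error(fisher_annotation(
    matrix(TRUE, 1, 1, dimnames = list("x", "c")),
    matrix(TRUE, 1, 1, dimnames = list("y", "r"))), "empty shared")
})
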