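test_that("aggregation respects the minimum-cell rule and conserves counts", {
  set.seed(1)
  n1 <- 19; n2 <- 20
  counts <- count_matrix(matrix(rpois(10 * (n1 + n2), 5), 10),
                         gene_ids = paste0("g", 1:10),
                         cell_ids = paste0("c", seq_len(n1 + n2)))
  cells <- cell_table(colnames(counts),
                      c(rep("sA", n1), rep("sB", n2)),
                      c(rep("control", n1), rep("cKO", n2)))
  pb <- aggregate_pseudobulk(counts, rep(1L, n1 + n2), cells)
  expect_equal(ncol(pb$counts), 1L)               # 19-cell aggregate dropped
  expect_equal(pb$samples$sample_id, "sB")
  expect_equal(unname(pb$counts[, 1]),
               unname(Matrix::rowSums(counts[, cells$sample_id == "sB"])))
  expect_length(pb$analyzable_clusters, 0)

  # synthetic defaults: 8 samples x 5 populations, all large -> 40 aggregates
  sim <- simulate_waterfall(simulation_design(
    cells_per_sample = 300, n_genes = 300, markers_per_population = 5,
    n_gradient_genes = 30, qc_fail_fraction = 0, seed = 2))
  labels <- as.integer(factor(sim$cells$truth_label))
  pb2 <- aggregate_pseudobulk(sim$counts, labels, sim$cells)
  expect_equal(ncol(pb2$counts), 40L)
  expect_setequal(pb2$analyzable_clusters, 1:5)
  expect_equal(sum(pb2$counts), sum(sim$counts))
})

test_that("the DE gene filter applies both the CPM and detection rules", {
  y <- rbind(a = c(100, 100, 100, 0, 0, 0),
             b = c(100, 100, 100, 100, 100, 100),
             z = c(0, 0, 0, 0, 0, 0),
             d = c(5000, 5000, 5000, 5000, 5000, 5000))
  det <- c(a = 25, b = 19, z = 0, d = 100)
  keep <- filter_de_genes(y, det)
  expect_false(keep[["b"]])      # detected in only 19 cells
  expect_false(keep[["z"]])      # all-zero
  expect_true(keep[["d"]])

  # brute-force cross-check on a random table
  set.seed(3)
  yr <- matrix(rnbinom(50 * 6, mu = 30, size = 2), 50, 6)
  rownames(yr) <- paste0("g", 1:50)
  detr <- setNames(sample(0:100, 50, replace = TRUE), rownames(yr))
  cpm <- sweep(yr, 2, colSums(yr), "/") * 1e6
  brute <- rowSums(cpm > 1) >= 3 & detr >= 20
  expect_equal(filter_de_genes(yr, detr), brute)
})

test_that("TMM factors match the step-by-step oracle and edgeR", {
  y <- matrix(rep(c(10, 40, 90, 3, 60), 4), ncol = 4)
  rownames(y) <- paste0("g", 1:5)
  expect_equal(unname(tmm_factors(y)), rep(1, 4))

  y2 <- y; y2[, 2] <- y2[, 2] * 2       # uniform scaling: CPM unchanged
  expect_equal(unname(tmm_factors(y2)), rep(1, 4))

  set.seed(4)
  toy <- matrix(rnbinom(1000 * 3, mu = 100, size = 5), 1000, 3)
  toy[1:100, 2] <- toy[1:100, 2] * 2L   # 10% of genes doubled in column 2
  rownames(toy) <- paste0("g", 1:1000)
  f <- tmm_factors(toy)
  expect_equal(unname(f), tmm_oracle(toy), tolerance = 1e-10)
  expect_equal(unname(f), unname(edgeR::calcNormFactors(toy, method = "TMM")),
               tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # invariant to gene order
  set.seed(5)
  perm <- sample(1000)
  expect_equal(unname(tmm_factors(toy[perm, ])), unname(f),
               tolerance = 1e-12)

  expect_error(tmm_factors(cbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(tmm_factors(y[, 1, drop = FALSE]), "at least 2")
})

test_that("the NB GLM matches the Poisson GLM in the zero-dispersion limit", {
  set.seed(1)
  y <- matrix(rpois(5 * 6, lambda = 20), 5, 6)
  rownames(y) <- paste0("g", 1:5)
  off <- log(colSums(y))
  x <- c(0, 0, 0, 1, 1, 1)
  full <- scwaterfall:::nbglm_fit(y, off, x, phi = 1e-9)
  null <- scwaterfall:::nbglm_fit(y, off, NULL, phi = 1e-9)
  lrt <- 2 * (full$ll - null$ll)
  lrt_glm <- vapply(1:5, function(g) {
    f1 <- glm(y[g, ] ~ x + offset(off), family = poisson())
    f0 <- glm(y[g, ] ~ 1 + offset(off), family = poisson())
    f0$deviance - f1$deviance
  }, numeric(1))
  expect_equal(lrt, lrt_glm, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("an all-zero-vs-large gene is called DE with the right sign", {
  set.seed(2)
  y <- matrix(rnbinom(200 * 8, mu = 50, size = 10), 200, 8)
  y[1, ] <- c(0, 0, 0, 0, 400, 420, 390, 410)   # zero in control, high in cKO
  rownames(y) <- sprintf("g%03d", 1:200)
  de <- nbglm_de(make_pb(y), 1)
  expect_lt(de$q[de$gene_id == "g001"], 0.05)
  expect_gt(de$log2fc[de$gene_id == "g001"], 0)
  expect_true(de$de[de$gene_id == "g001"])
  expect_true(all(de$p >= 0 & de$p <= 1))
})

test_that("the common dispersion estimate recovers the truth", {
  set.seed(6)
  y <- matrix(rnbinom(2000 * 8, mu = 50, size = 1 / 0.1), 2000, 8)
  rownames(y) <- sprintf("g%04d", 1:2000)
  de <- nbglm_de(make_pb(y), 1)
  expect_equal(attr(de, "dispersion"), 0.1, tolerance = 0.15)
  # null fold-changes: sd(log2fc) ~ 0.35 at these counts, mean near zero
  expect_lt(abs(mean(de$log2fc)), 0.05)
  expect_lt(mean(abs(de$log2fc)), 0.5)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  m <- length(p)
  brute <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(bh_fdr(p), pmin(brute, 1))
  # monotone in p
  expect_true(all(diff(bh_fdr(sort(runif(50)))) >= 0))
})

test_that("the gene-set test reduces to a z-test at rho = 0 and is
           monotone in rho", {
  set.seed(7)
  z <- rnorm(500)
  names(z) <- sprintf("g%03d", 1:500)
  sets <- list(S1 = names(z)[1:30], S2 = names(z)[31:80])

  res0 <- camera_test(z, sets, rho = 0)
  for (nm in names(sets)) {
    m <- length(sets[[nm]]); G <- length(z)
    inset <- names(z) %in% sets[[nm]]
    delta <- mean(z[inset]) - mean(z[!inset])
    pz <- 2 * pnorm(-abs(delta) / sqrt((1 / m + 1 / (G - m)) * var(z)))
    expect_equal(res0$p[res0$set == nm], pz, tolerance = 1e-12)
  }

  rhos <- c(0, 0.005, 0.01, 0.05, 0.2)
  pvals <- vapply(rhos, function(r) camera_test(z, sets, rho = r)$p[1],
                  numeric(1))
  expect_true(all(diff(pvals) >= 0))

  # sets at or below ten genes are skipped
  small <- list(TINY = names(z)[1:10])
  expect_equal(nrow(camera_test(z, small)), 0)
})

test_that("set p-values are uniform under random set membership", {
  # randomly drawn sets have no true inter-gene correlation, so the
  # un-inflated (rho = 0) statistic must be exactly calibrated; positive
  # rho is conservative by design (covered by the monotonicity test)
  set.seed(8)
  z <- rnorm(800)
  names(z) <- sprintf("g%03d", 1:800)
  p <- vapply(1:500, function(i) {
    camera_test(z, list(S = sample(names(z), 40)), rho = 0)$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("signed z-scores carry the fold-change sign", {
  de <- tibble::tibble(cluster = 1, gene_id = c("a", "b"),
                       log2fc = c(2, -1), lrt = c(9, 4),
                       p = c(0.01, 0.04), q = c(0.02, 0.04),
                       de = c(TRUE, TRUE))
  z <- de_zscores(de)
  expect_equal(unname(z), c(3, -2))
})
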