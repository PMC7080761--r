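grid81 <- function(seed = 5, spacing = 10) {
  set.seed(seed)
  pts <- as.matrix(expand.grid(x = seq(0, 80, spacing),
                               y = seq(0, 80, spacing)))
  pts <- pts[sample(81), ] + matrix(rnorm(162, 0, 0.01), 81, 2)
  rownames(pts) <- paste0("p", seq_len(81))
  pts
}

test_that("the batch SOM converges onto well-separated points", {
  pts <- grid81()
  som <- train_som(pts, grid = c(9, 9), seed = 1, epochs = 30)
  qe <- mean(sqrt(rowSums((pts - som$codebook[som$assignment, ])^2)))
  expect_lt(qe, 10 / 10)              # below inter-point spacing / 10

  som2 <- train_som(pts, grid = c(9, 9), seed = 1, epochs = 30)
  expect_identical(som$codebook, som2$codebook)

  const <- matrix(5, 200, 7)
  rownames(const) <- paste0("c", 1:200)
  sc <- train_som(const, seed = 2)
  expect_equal(as.vector(sc$codebook), rep(5, length(sc$codebook)),
               tolerance = 1e-8)

  expect_error(train_som(pts[1:50, ], grid = c(9, 9)), "smaller grid")
})

test_that("every cell maps to its true nearest codebook vector", {
  set.seed(8)
  x <- matrix(rnorm(1000 * 10), 1000, 10)
  rownames(x) <- paste0("c", 1:1000)
  som <- train_som(x, grid = c(5, 5), seed = 1)
  brute <- apply(x, 1, function(p) {
    which.min(colSums((t(som$codebook) - p)^2))
  })
  expect_equal(unname(som$assignment), unname(brute))
})

test_that("the MST is minimal, spanning, and deterministic", {
  # 3 nodes with pairwise distances 1, 2, 3: tree keeps the 1 and 2 edges
  cb <- matrix(c(0, 1, 3), ncol = 1)
  rownames(cb) <- paste0("n", 1:3)
  e <- som_mst(cb)
  expect_equal(nrow(e), 2)
  expect_equal(sort(e$weight), c(1, 2))
  expect_false(any(e$from == 1 & e$to == 3))

  set.seed(3)
  cb2 <- matrix(rnorm(81 * 5), 81, 5)
  e2 <- som_mst(cb2)
  expect_equal(nrow(e2), 80)
  # spans all nodes
  expect_setequal(unique(c(e2$from, e2$to)), 1:81)
  # total weight no larger than a star tree's
  star <- sum(sqrt(colSums((t(cb2[-1, ]) - cb2[1, ])^2)))
  expect_lte(sum(e2$weight), star)

  # duplicate nodes give zero-weight edges
  cb3 <- matrix(c(0, 0, 5), ncol = 1)
  rownames(cb3) <- paste0("n", 1:3)
  expect_equal(min(som_mst(cb3)$weight), 0)
})

test_that("node condition enrichment normalizes by condition totals", {
  cells <- cell_table(paste0("c", 1:30), "s",
                      c(rep("control", 20), rep("cKO", 10)))
  # node 1 mirrors the global composition (2:1), node 2 all cKO,
  # node 3 all control
  assignment <- stats::setNames(
    c(rep(1, 12), rep(3, 8), rep(1, 6), rep(2, 4)), cells$cell_id)
  enr <- node_condition_enrichment(assignment, cells)
  expect_equal(enr$cko_share[enr$node == 1], 0.5)
  expect_equal(enr$cko_share[enr$node == 2], 1)
  expect_equal(enr$cko_share[enr$node == 3], 0)
  expect_equal(sum(enr$n_control) + sum(enr$n_cko), 30L)

  # hand-computed three-node case with unequal totals
  # node: 5 of 20 control (rate .25), 4 of 10 cKO (rate .4)
  cells2 <- cells
  a2 <- stats::setNames(c(rep(1, 5), rep(2, 15), rep(1, 4), rep(2, 6)),
                        cells2$cell_id)
  enr2 <- node_condition_enrichment(a2, cells2)
  expect_equal(enr2$cko_share[enr2$node == 1], 0.4 / (0.4 + 0.25))
})

test_that("the KDE is a proper, translation-equivariant density", {
  set.seed(2)
  pts <- cbind(rnorm(2000), rnorm(2000, sd = 2))
  k <- kde2d_density(pts)
  expect_true(all(k$z >= 0))
  integral <- sum(k$z) * diff(k$x)[1] * diff(k$y)[1]
  expect_equal(integral, 1, tolerance = 1e-3)

  shift <- kde2d_density(sweep(pts, 2, c(3, -1), "+"))
  expect_equal(shift$x, k$x + 3, tolerance = 1e-12)
  expect_equal(shift$y, k$y - 1, tolerance = 1e-12)
  expect_equal(shift$z, k$z, tolerance = 1e-12)

  degenerate <- cbind(rep(1, 10), rnorm(10))
  expect_error(kde2d_density(degenerate), "zero spread")
  expect_error(kde2d_density(pts[1, , drop = FALSE]), "at least 2")
})

test_that("differential density is antisymmetric and sign-faithful", {
  set.seed(5)
  a <- cbind(rnorm(800), rnorm(800))
  b <- cbind(rnorm(800, mean = 3), rnorm(800))
  lim <- list(range(c(a[, 1], b[, 1])) + c(-0.5, 0.5),
              range(c(a[, 2], b[, 2])) + c(-0.5, 0.5))
  ka <- kde2d_density(a, limits = lim)
  kb <- kde2d_density(b, limits = lim)

  expect_equal(differential_density(ka, ka)$z,
               matrix(0, 100, 100), ignore_attr = TRUE)
  d_ab <- differential_density(ka, kb)
  d_ba <- differential_density(kb, ka)
  expect_identical(d_ab$z, -d_ba$z)

  # cKO = b (offset +3): positive log-ratio on b's side, negative on a's
  d <- differential_density(kb, ka)
  at <- function(m, x, y) m$z[which.min(abs(m$x - x)), which.min(abs(m$y - y))]
  expect_gt(at(d, 3, 0), 0)
  expect_lt(at(d, 0, 0), 0)
  # sign flips where the analytic ratio crosses 1 (midpoint x = 1.5)
  expect_gt(at(d, 2.5, 0), 0)
  expect_lt(at(d, 0.5, 0), 0)

  kc <- kde2d_density(a)
  expect_error(differential_density(ka, kc), "grids differ")
})

test_that("condition density maps share one grid and expose the log ratio", {
  set.seed(6)
  coords <- rbind(cbind(rnorm(300), rnorm(300)),
                  cbind(rnorm(300, 2), rnorm(300)))
  cells <- cell_table(paste0("c", 1:600), "s",
                      rep(c("control", "cKO"), each = 300))
  maps <- condition_density_maps(coords, cells)
  expect_equal(maps$control$x, maps$cko$x)
  expect_equal(maps$diff$z,
               log2((maps$cko$z + 1e-3) / (maps$control$z + 1e-3)))
})
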