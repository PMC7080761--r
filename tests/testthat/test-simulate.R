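test_that("the generator is deterministic given the seed", {
  s1 <- simulate_waterfall(small_design(seed = 11))
  s2 <- simulate_waterfall(small_design(seed = 11))
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cells, s2$cells)
  s3 <- simulate_waterfall(small_design(seed = 12))
  expect_false(identical(as.matrix(s1$counts), as.matrix(s3$counts)))
})

test_that("without planted failures every cell passes default QC", {
  sim <- simulate_waterfall(simulation_design(
    cells_per_sample = 150, n_genes = 2000, qc_fail_fraction = 0,
    hemoglobin_cell_fraction = 0, seed = 3))
  qc <- cell_qc_mask(compute_qc_metrics(sim$counts, sim$genes))
  expect_true(all(qc$keep))
})

test_that("identical compositions and unit fold make conditions exchangeable", {
  # same composition for both conditions and no planted expression effect:
  # the early-monocyte frequency difference should be non-significant at
  # alpha = 0.05 in at least 95% of seeds
  p <- vapply(1:100, function(s) {
    des <- simulation_design(
      cells_per_sample = 120, n_genes = 200, markers_per_population = 5,
      n_gradient_genes = 30, apoptosis_cko_fold = 1,
      composition_cko = c(0.15, 0.20, 0.20, 0.20, 0.25),
      qc_fail_fraction = 0, hemoglobin_cell_fraction = 0, seed = s)
    sim <- simulate_waterfall(des)
    tab <- table(sim$cells$condition, sim$cells$truth_label == "mono_early")
    suppressWarnings(stats::prop.test(tab)$p.value)
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.95)
})

test_that("the planted composition shift is recovered at alpha 0.01", {
  sim <- simulate_waterfall(simulation_design(
    n_genes = 300, markers_per_population = 5, n_gradient_genes = 30,
    seed = 5))
  cond <- sim$cells$condition
  early <- sim$cells$truth_label == "mono_early"
  mature <- sim$cells$truth_label == "mac_mature"
  p_early <- stats::prop.test(table(cond, early))$p.value
  p_mature <- stats::prop.test(table(cond, mature))$p.value
  expect_lt(p_early, 0.01)
  expect_lt(p_mature, 0.01)
  expect_gt(mean(early[cond == "cKO"]), mean(early[cond == "control"]))
  expect_lt(mean(mature[cond == "cKO"]), mean(mature[cond == "control"]))
})

test_that("marginal gene means converge to the mixture of population means", {
  des <- simulation_design(
    n_samples_per_condition = 4, cells_per_sample = 1250, n_genes = 300,
    markers_per_population = 5, n_gradient_genes = 30,
    apoptosis_cko_fold = 1,
    composition_cko = c(0.15, 0.20, 0.20, 0.20, 0.25),
    qc_fail_fraction = 0, hemoglobin_cell_fraction = 0, seed = 8)
  sim <- simulate_waterfall(des)         # 10,000 cells
  pi <- des$composition_control
  expected <- as.numeric(sim$model$mu %*% pi)   # mean size factor is 1
  observed <- Matrix::rowMeans(sim$counts)
  sel <- expected > 1
  rel <- abs(observed[sel] - expected[sel]) / expected[sel]
  expect_lt(max(rel), 0.05)
})

test_that("reference profiles match their populations and flag markers", {
  des <- small_design(seed = 2)
  ref <- simulate_reference(des)
  expect_setequal(ref$labels, c("monocyte", "macrophage", "dc", "lymphoid",
                                "stromal"))
  sim <- simulate_waterfall(des)
  sym <- sim$genes$symbol
  for (mk in c("Ccr2", "Ly6c2", "Cd14")) {
    expect_true(ref$binary[which(sym == mk), "monocyte"])
  }
  # expressed set of the matched reference overlaps the population's own
  # expressed set by at least 70%
  pop_cpm <- sweep(sim$model$mu, 2, colSums(sim$model$mu), "/") * 1e6
  pop_bin <- pop_cpm[, "mono_early"] > ref$expressed_cpm_cut
  ref_bin <- ref$binary[, "monocyte"]
  expect_gte(sum(ref_bin & pop_bin) / sum(ref_bin), 0.7)
})

test_that("truth export round trips and preserves label counts", {
  sim <- simulate_waterfall(small_design(seed = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$cell_id, sim$truth$cell_id)
  expect_equal(table(back$truth_label), table(sim$truth$truth_label))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_truth(sim$truth[0, ], f2)
  expect_equal(nrow(read_truth(f2)), 0)
})

test_that("degenerate designs are rejected", {
  expect_error(simulation_design(n_genes = 0), "degenerate")
  expect_error(simulation_design(cells_per_sample = 0), "degenerate")
  expect_error(simulation_design(composition_control = c(1, 1, 1, 1, 1)),
               "sum to 1")
  expect_error(simulation_design(apoptosis_cko_fold = 0), "positive")
})

test_that("a simulated experiment writes a loadable 10x directory tree", {
  d <- withr::local_tempdir()
  sim <- simulate_waterfall(small_design(seed = 6))
  sheet_path <- write_simulated_experiment(sim, d)
  sheet <- read_sample_sheet(sheet_path)
  expect_equal(nrow(sheet), 8)
  x <- read_10x_mtx(sheet$path[1])
  in_sample <- sim$cells$sample_id == sheet$sample_id[1]
  expect_equal(as.matrix(x$counts),
               as.matrix(sim$counts[, in_sample]), ignore_attr = TRUE)
})
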