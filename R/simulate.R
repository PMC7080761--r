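#' Default populations of the simulated differentiation trajectory
#'
#' Five trajectory-ordered populations emulating the stepwise development of
#' Ly6C-high blood monocytes into mature MHCII+ colonic macrophages, with
#' optional contaminant populations (dendritic cells, lymphoid cells,
#' stromal cells) off the trajectory.
#'
#' @param include_contaminants Add the three contaminant populations.
#' @return A tibble with columns `name`, `position` (trajectory position in
#'   `[0,1]`, `NA` for contaminants) and `is_contaminant`.
#' @export
default_populations <- function(include_contaminants = FALSE) {
  pops <- tibble::tibble(
    name = c("mono_early", "mono_late", "mac_early", "mac_inter", "mac_mature"),
    position = c(0, 0.25, 0.5, 0.75, 1),
    is_contaminant = FALSE
  )
  if (include_contaminants) {
    pops <- dplyr::bind_rows(pops, tibble::tibble(
      name = c("dc", "lymphoid", "stromal"),
      position = NA_real_,
      is_contaminant = TRUE
    ))
  }
  pops
}

default_marker_modules <- function() {
  # Readable marker symbols for the trajectory endpoints; the remaining
  # markers are generated per population. Monocytes: Ccr2/Ly6c2/Cd14;
  # macrophages: Cx3cr1/Adgre1/Cd81/Cd74/Cd72 and the EYFP reporter.
  list(
    mono_early = c("Ccr2", "Ly6c2", "Cd14"),
    mono_late  = c("Ly6c1", "Ccr2l"),
    mac_early  = c("Cd63", "Mafb"),
    mac_inter  = c("Cd74", "Cd72"),
    mac_mature = c("Cx3cr1", "Adgre1", "Cd81", "EYFP"),
    dc         = c("Flt3", "Cd209a"),
    lymphoid   = c("Cd3e", "Cd19"),
    stromal    = c("Col1a1", "Pdgfra")
  )
}

#' Symbols of the planted apoptosis gene module
#'
#' Six canonical apoptosis genes plus generated module members; the set the
#' simulation upregulates in cKO monocytes, usable directly as a gene set
#' for [camera_test()].
#'
#' @return A character vector of 20 symbols.
#' @export
default_apoptosis_genes <- function() {
  c("Bcl2l11", "Casp3", "Osm", "Fos", "Tnf", "Fas",
    sprintf("ApoptMod%02d", 1:14))
}

#' Specify a synthetic waterfall experiment
#'
#' Defines the generative model for genotype-contrasted UMI counts with
#' known truth: negative-binomial counts with cell-specific size factors,
#' five trajectory-ordered populations whose non-marker "gradient" genes
#' interpolate log-means linearly along the trajectory, per-population marker
#' modules, a planted apoptosis module upregulated in cKO monocytes, a
#' planted composition shift (cKO enriched in the early-monocyte population
#' and depleted in the mature-macrophage population), and planted QC-failing
#' and hemoglobin-contaminated cells.
#'
#' @param n_samples_per_condition Samples per condition (default 4).
#' @param cells_per_sample Cells per sample (default 400).
#' @param n_genes Number of genes (default 2000, including the mitochondrial
#'   and hemoglobin genes).
#' @param populations Tibble from [default_populations()].
#' @param composition_control,composition_cko Probability vectors over
#'   populations (must sum to 1).
#' @param markers_per_population Generated marker genes per population.
#' @param marker_log2fc Marker log2 fold-change over baseline in the target
#'   population (adjacent trajectory populations receive a third of it, so
#'   expression changes smoothly along the waterfall).
#' @param n_gradient_genes Genes whose log-mean interpolates linearly between
#'   trajectory endpoints.
#' @param apoptosis_genes Symbols of the planted apoptosis module.
#' @param apoptosis_cko_fold Fold-change of the module in cKO cells of the
#'   monocyte populations (default 2).
#' @param mean_libsize Target mean library size of a clean cell (UMIs).
#' @param size_factor_sigma Log-normal sigma of cell size factors.
#' @param dispersion_range Range of the NB dispersion (variance =
#'   mu + phi mu^2); phi decreases with gene mean within this range.
#' @param qc_fail_fraction Fraction of planted QC-failing cells per sample
#'   (half tiny library, half high mitochondrial content).
#' @param hemoglobin_cell_fraction Fraction of cells given hemoglobin UMIs.
#' @param seed Integer seed; the generator is deterministic given the design.
#' @return A `waterfall_design` object (named list).
#' @export
simulation_design <- function(n_samples_per_condition = 4,
                              cells_per_sample = 400,
                              n_genes = 2000,
                              populations = default_populations(),
                              composition_control = c(0.15, 0.20, 0.20, 0.20, 0.25),
                              composition_cko = c(0.30, 0.22, 0.20, 0.16, 0.12),
                              markers_per_population = 40,
                              marker_log2fc = 3,
                              n_gradient_genes = 300,
                              apoptosis_genes = default_apoptosis_genes(),
                              apoptosis_cko_fold = 2.0,
                              mean_libsize = 3000,
                              size_factor_sigma = 0.3,
                              dispersion_range = c(0.05, 0.5),
                              qc_fail_fraction = 0.05,
                              hemoglobin_cell_fraction = 0.01,
                              seed = 1L) {
  npop <- nrow(populations)
  if (npop < 2) stop("need at least 2 populations")
  if (n_genes < 1 || cells_per_sample < 1 || n_samples_per_condition < 1) {
    stop("degenerate design: zero genes, cells or samples")
  }
  for (comp in list(composition_control, composition_cko)) {
    if (length(comp) != npop) stop("composition length != number of populations")
    if (any(comp < 0) || abs(sum(comp) - 1) > 1e-8) {
      stop("compositions must be nonnegative and sum to 1")
    }
  }
  if (apoptosis_cko_fold <= 0 || marker_log2fc < 0) {
    stop("fold-changes must be positive")
  }
  structure(list(
    n_samples_per_condition = as.integer(n_samples_per_condition),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes),
    populations = populations,
    composition_control = composition_control,
    composition_cko = composition_cko,
    markers_per_population = as.integer(markers_per_population),
    marker_log2fc = marker_log2fc,
    n_gradient_genes = as.integer(n_gradient_genes),
    apoptosis_genes = apoptosis_genes,
    apoptosis_cko_fold = apoptosis_cko_fold,
    mean_libsize = mean_libsize,
    size_factor_sigma = size_factor_sigma,
    dispersion_range = dispersion_range,
    qc_fail_fraction = qc_fail_fraction,
    hemoglobin_cell_fraction = hemoglobin_cell_fraction,
    seed = as.integer(seed)
  ), class = "waterfall_design")
}

mito_symbols <- function() {
  c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3", "mt-Atp6", "mt-Atp8",
    "mt-Cytb", "mt-Nd3", "mt-Nd4", "mt-Nd4l", "mt-Nd5", "mt-Nd6")
}

hemoglobin_symbols <- function() {
  c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt")
}

# Build the per-population mean model: a genes x populations matrix of
# expected counts for a size-factor-1 cell, plus gene bookkeeping.
build_mean_model <- function(design) {
  pops <- design$populations
  npop <- nrow(pops)
  n_genes <- design$n_genes
  mito <- mito_symbols()
  hb <- hemoglobin_symbols()
  apop <- design$apoptosis_genes
  named <- unlist(default_marker_modules(), use.names = FALSE)

  n_special <- length(mito) + length(hb) + length(apop)
  if (n_genes < n_special + npop * design$markers_per_population +
      design$n_gradient_genes) {
    stop("n_genes too small for the requested modules")
  }

  symbols <- character(n_genes)
  gene_id <- sprintf("SIMG%05d", seq_len(n_genes))

  idx <- 1L
  take <- function(k) {
    out <- idx:(idx + k - 1L)
    idx <<- idx + k
    out
  }
  mito_idx <- take(length(mito)); symbols[mito_idx] <- mito
  hb_idx <- take(length(hb)); symbols[hb_idx] <- hb
  apop_idx <- take(length(apop)); symbols[apop_idx] <- apop

  marker_idx <- list()
  modules <- default_marker_modules()
  for (p in seq_len(npop)) {
    nm <- pops$name[p]
    seed_syms <- modules[[nm]]
    if (is.null(seed_syms)) seed_syms <- character(0)
    n_gen <- max(design$markers_per_population - length(seed_syms), 0L)
    ii <- take(length(seed_syms) + n_gen)
    symbols[ii] <- c(seed_syms, sprintf("%sMk%02d", nm, seq_len(n_gen)))
    marker_idx[[nm]] <- ii
  }
  grad_idx <- take(design$n_gradient_genes)
  symbols[grad_idx] <- sprintf("Grad%04d", seq_along(grad_idx))
  rest_idx <- if (idx <= n_genes) idx:n_genes else integer(0)
  symbols[rest_idx] <- sprintf("Gene%05d", seq_along(rest_idx))

  # cell-type expression programs: half of the housekeeping bulk is ON only
  # inside a window of the trajectory and silenced elsewhere, giving the
  # clearly bimodal expressed/not-expressed structure of real pseudo-bulk
  # profiles
  program_idx <- rest_idx[seq_len(floor(length(rest_idx) / 2))]
  program_anchor <- stats::runif(length(program_idx))
  program_width <- stats::runif(length(program_idx), 0.3, 0.9)

  # Baseline log2 means: long-tailed, later rescaled to the target library
  # size. Mito genes get a fixed budget of ~2% of the library; hemoglobin
  # genes are silent except in planted contaminated cells.
  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  base[hb_idx] <- 0
  base[apop_idx] <- stats::runif(length(apop_idx), 2, 5)

  L <- matrix(rep(log2(base + 1e-6), npop), ncol = npop,
              dimnames = list(gene_id, pops$name))

  # gradient genes: linear interpolation of log-means along the trajectory
  delta <- stats::rnorm(length(grad_idx), 0, 1.5)
  traj <- which(!pops$is_contaminant)
  for (p in traj) {
    L[grad_idx, p] <- L[grad_idx, p] + delta * pops$position[p]
  }

  # marker modules: strong in the target population, a third of the effect
  # in trajectory neighbours, so the waterfall stays a continuum
  for (p in seq_len(npop)) {
    nm <- pops$name[p]
    ii <- marker_idx[[nm]]
    L[ii, p] <- L[ii, p] + design$marker_log2fc
    if (!pops$is_contaminant[p]) {
      for (q in traj) {
        if (q != p && abs(pops$position[q] - pops$position[p]) <= 0.26) {
          L[ii, q] <- L[ii, q] + design$marker_log2fc / 3
        }
      }
    }
  }

  mu <- 2^L
  silence_factor <- 0.02
  for (p in seq_len(npop)) {
    if (pops$is_contaminant[p]) {
      off <- stats::runif(length(program_idx)) < 0.4
    } else {
      off <- abs(pops$position[p] - program_anchor) > program_width / 2
    }
    mu[program_idx[off], p] <- mu[program_idx[off], p] * silence_factor
  }
  mu[hb_idx, ] <- 0
  # mitochondrial budget: ~2% of each population's library
  for (p in seq_len(npop)) {
    tot <- sum(mu[-c(mito_idx, hb_idx), p])
    mu[mito_idx, p] <- 0.02 * tot / length(mito_idx)
  }
  # rescale every population to the target mean library size
  for (p in seq_len(npop)) {
    mu[, p] <- mu[, p] * design$mean_libsize / sum(mu[, p])
  }

  # NB dispersion on a decreasing trend in the gene mean
  mbar <- rowMeans(mu)
  r <- rank(mbar, ties.method = "first") / length(mbar)
  lo <- design$dispersion_range[1]
  hi <- design$dispersion_range[2]
  phi <- lo + (hi - lo) * (1 - r) + stats::runif(n_genes, 0, 0.02)
  phi <- pmin(pmax(phi, lo), hi)

  list(gene_id = gene_id, symbols = symbols, mu = mu, phi = phi,
       mito_idx = mito_idx, hb_idx = hb_idx, apop_idx = apop_idx,
       marker_idx = marker_idx, grad_idx = grad_idx,
       program_idx = program_idx, program_anchor = program_anchor,
       program_width = program_width, silence_factor = silence_factor)
}

#' Simulate a genotype-contrasted waterfall experiment
#'
#' Draws UMI counts as `NB(mean = s_c * mu[g, pop(c)], dispersion = phi_g)`
#' with log-normal cell size factors `s_c`; the population of each cell is
#' drawn from its condition's composition vector; the apoptosis-module means
#' are multiplied by `apoptosis_cko_fold` in cKO cells of the monocyte
#' populations; planted QC-failing cells get either a library size below the
#' QC threshold or a mitochondrial fraction above it, and planted
#' hemoglobin-contaminated cells get at least one hemoglobin UMI. The output
#' is deterministic given the design (including its seed).
#'
#' @param design A [simulation_design()].
#' @return A list with `counts` (sparse genes x cells matrix), `cells`
#'   (a [cell_table()] tibble with `truth_label`, `planted_qc_fail`,
#'   `planted_hemoglobin` columns), `genes` (a [gene_table()] tibble),
#'   `truth` (the same tibble, the per-cell ground truth) and `model`
#'   (the mean/dispersion model used).
#' @examples
#' sim <- simulate_waterfall(simulation_design(
#'   cells_per_sample = 50, n_genes = 600,
#'   markers_per_population = 10, n_gradient_genes = 50))
#' dim(sim$counts)
#' @export
simulate_waterfall <- function(design) {
  stopifnot(inherits(design, "waterfall_design"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(design$seed)

  model <- build_mean_model(design)
  pops <- design$populations
  npop <- nrow(pops)
  nspc <- design$n_samples_per_condition
  ncell <- design$cells_per_sample
  n_genes <- design$n_genes

  sample_ids <- c(sprintf("control_%d", seq_len(nspc)),
                  sprintf("cko_%d", seq_len(nspc)))
  conditions <- rep(c("control", "cKO"), each = nspc)

  apop_target <- pops$name[!pops$is_contaminant &
                             !is.na(pops$position) & pops$position <= 0.25]

  all_counts <- vector("list", length(sample_ids))
  all_cells <- vector("list", length(sample_ids))

  for (s in seq_along(sample_ids)) {
    cond <- conditions[s]
    comp <- if (cond == "control") design$composition_control else design$composition_cko
    pop_of <- sample.int(npop, ncell, replace = TRUE, prob = comp)
    sf <- stats::rlnorm(ncell, meanlog = -design$size_factor_sigma^2 / 2,
                        sdlog = design$size_factor_sigma)

    n_fail <- round(design$qc_fail_fraction * ncell)
    fail_idx <- if (n_fail > 0) sample.int(ncell, n_fail) else integer(0)
    small_lib <- fail_idx[seq_len(floor(n_fail / 2))]
    high_mito <- setdiff(fail_idx, small_lib)
    sf[small_lib] <- sf[small_lib] * 0.08

    n_hb <- round(design$hemoglobin_cell_fraction * ncell)
    hb_cells <- if (n_hb > 0) sample(setdiff(seq_len(ncell), fail_idx),
                                     min(n_hb, ncell - n_fail)) else integer(0)

    cm <- matrix(0L, nrow = n_genes, ncol = ncell)
    for (i in seq_len(ncell)) {
      mu_i <- model$mu[, pop_of[i]] * sf[i]
      if (cond == "cKO" && pops$name[pop_of[i]] %in% apop_target) {
        mu_i[model$apop_idx] <- mu_i[model$apop_idx] * design$apoptosis_cko_fold
      }
      if (i %in% high_mito) {
        # push the mitochondrial fraction to ~15%
        mu_i[model$mito_idx] <- mu_i[model$mito_idx] * 9
      }
      cm[, i] <- stats::rnbinom(n_genes, mu = mu_i, size = 1 / model$phi)
    }
    if (length(hb_cells)) {
      cm[model$hb_idx[1], hb_cells] <- cm[model$hb_idx[1], hb_cells] + 1L +
        stats::rpois(length(hb_cells), 1)
    }
    cell_ids <- sprintf("%s_cell%04d", sample_ids[s], seq_len(ncell))
    dimnames(cm) <- list(model$gene_id, cell_ids)
    all_counts[[s]] <- methods::as(Matrix::Matrix(cm, sparse = TRUE), "CsparseMatrix")
    ct <- cell_table(cell_ids, sample_ids[s], cond,
                     truth_label = pops$name[pop_of])
    ct$planted_qc_fail <- seq_len(ncell) %in% fail_idx
    ct$planted_hemoglobin <- seq_len(ncell) %in% hb_cells
    all_cells[[s]] <- ct
  }

  counts <- do.call(cbind, all_counts)
  cells <- dplyr::bind_rows(all_cells)
  genes <- gene_table(model$gene_id, model$symbols)
  list(counts = counts, cells = cells, genes = genes, truth = cells,
       model = model, design = design)
}

#' Simulate annotation reference profiles
#'
#' Builds per-cell-type reference expression profiles (mean profile, binary
#' expressed profile, label) standing in for a curated immune-cell reference
#' compendium. The monocyte and macrophage references are derived from the
#' simulated trajectory populations (so a matched reference shares most of
#' its expressed genes with the matching population); dendritic, lymphoid
#' and stromal references carry their own marker modules. A gene is called
#' expressed in a reference when its CPM exceeds `expressed_cpm_cut`.
#'
#' @param design A [simulation_design()].
#' @param expressed_cpm_cut CPM above which a reference gene counts as
#'   expressed (default 100).
#' @return A list with `profiles` (genes x types CPM matrix), `binary`
#'   (logical genes x types), `labels` and the cut used.
#' @export
simulate_reference <- function(design, expressed_cpm_cut = 100) {
  stopifnot(inherits(design, "waterfall_design"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  # the gene model must reproduce the simulation's draws exactly, so the
  # references describe the same genes; only the contaminant-specific
  # programs below use an independent stream
  set.seed(design$seed)
  model <- build_mean_model(design)
  set.seed(design$seed + 104729L)
  pops <- design$populations
  traj <- !pops$is_contaminant
  mono_cols <- which(traj & pops$position <= 0.25)
  mac_cols <- which(traj & pops$position >= 0.75)

  base <- rowMeans(model$mu)
  # the unsilenced (ON) level of every expression-program gene
  base_on <- base
  base_on[model$program_idx] <- apply(
    model$mu[model$program_idx, , drop = FALSE], 1, max)
  mk <- function(cols) rowMeans(model$mu[, cols, drop = FALSE])
  contam_profile <- function(nm) {
    prof <- base_on
    # an independent expression program distinguishes off-trajectory types
    off <- stats::runif(length(model$program_idx)) < 0.4
    prof[model$program_idx[off]] <- prof[model$program_idx[off]] *
      model$silence_factor
    ii <- model$marker_idx[[nm]]
    if (is.null(ii)) {
      modules <- default_marker_modules()
      syms <- modules[[nm]]
      ii <- match(syms, model$symbols)
      ii <- ii[!is.na(ii)]
      if (!length(ii)) {
        ii <- sample(model$grad_idx, design$markers_per_population)
      }
    }
    prof[ii] <- prof[ii] * 2^design$marker_log2fc
    # damp trajectory markers so contaminants do not look like the waterfall
    for (jj in model$marker_idx) prof[setdiff(jj, ii)] <- prof[setdiff(jj, ii)] * 0.25
    prof
  }

  profiles <- cbind(
    monocyte = mk(mono_cols),
    macrophage = mk(mac_cols),
    dc = contam_profile("dc"),
    lymphoid = contam_profile("lymphoid"),
    stromal = contam_profile("stromal")
  )
  rownames(profiles) <- model$gene_id
  cpm <- sweep(profiles, 2, colSums(profiles), "/") * 1e6
  binary <- cpm > expressed_cpm_cut
  list(profiles = cpm, binary = binary, labels = colnames(profiles),
       expressed_cpm_cut = expressed_cpm_cut)
}

#' Export per-cell ground truth to TSV
#'
#' @param truth The `truth` tibble of [simulate_waterfall()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported truth table
#' @param path TSV written by [export_truth()].
#' @return A tibble.
#' @export
read_truth <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a simulated experiment as per-sample 10x directories
#'
#' Materializes the synthetic experiment as one MatrixMarket triplet
#' directory per sample plus a sample sheet and a truth TSV, i.e. the same
#' on-disk layout a real experiment enters the pipeline with.
#'
#' @param sim Output of [simulate_waterfall()].
#' @param outdir Output directory.
#' @return The sample sheet path, invisibly.
#' @export
write_simulated_experiment <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sheet <- dplyr::distinct(sim$cells, .data$sample_id, .data$condition)
  sheet$path <- file.path(outdir, sheet$sample_id)
  for (i in seq_len(nrow(sheet))) {
    keep <- sim$cells$sample_id == sheet$sample_id[i]
    write_10x_mtx(sim$counts[, keep, drop = FALSE], sim$genes, sheet$path[i])
  }
  sheet_path <- file.path(outdir, "samples.tsv")
  write.table(sheet[, c("sample_id", "path", "condition")], sheet_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  export_truth(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(sheet_path)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
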