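#' Construct a validated UMI count matrix
#'
#' Counts are stored genes-as-rows in a sparse integer-valued matrix with
#' unique gene and cell identifiers on the dimnames. All entries must be
#' nonnegative integers.
#'
#' @param values A matrix or sparse Matrix, genes x cells.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell identifiers (columns).
#' @return A `dgCMatrix` with dimnames set, validated.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(m)) stop("gene_ids length != number of rows")
  if (length(cell_ids) != ncol(m)) stop("cell_ids length != number of columns")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("count matrix entries must be nonnegative integers")
  }
  dimnames(m) <- list(gene_ids, cell_ids)
  m
}

#' Build a gene table with mitochondrial / hemoglobin flags
#'
#' Mitochondrial genes are recognized by a case-insensitive symbol prefix
#' (default `"mt-"`), hemoglobin genes by a configurable prefix list
#' (default `Hba*`/`Hbb*`); neither list is hard-coded elsewhere.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param symbol Character vector of gene symbols (same length).
#' @param config An [analysis_config()] supplying the prefixes.
#' @return A tibble with columns `gene_id`, `symbol`, `is_mito`,
#'   `is_hemoglobin`.
#' @export
gene_table <- function(gene_id, symbol = gene_id, config = analysis_config()) {
  stopifnot(length(gene_id) == length(symbol), !anyDuplicated(gene_id))
  sym <- as.character(symbol)
  hb_pat <- paste0("^(", paste(config$hemoglobin_prefixes, collapse = "|"), ")")
  tibble::tibble(
    gene_id = as.character(gene_id),
    symbol = sym,
    is_mito = startsWith(tolower(sym), tolower(config$mito_prefix)),
    is_hemoglobin = grepl(hb_pat, sym)
  )
}

#' Build a per-cell metadata table
#'
#' @param cell_id,sample_id,condition Character vectors of equal length;
#'   `condition` must be `"control"` or `"cKO"`.
#' @param truth_label Optional known population labels (synthetic data only).
#' @return A tibble with one row per cell.
#' @export
cell_table <- function(cell_id, sample_id, condition, truth_label = NA_character_) {
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), c("control", "cKO"))
  if (length(bad)) stop("condition must be 'control' or 'cKO', got: ",
                        paste(bad, collapse = ", "))
  tibble::tibble(
    cell_id = as.character(cell_id),
    sample_id = as.character(sample_id),
    condition = condition,
    truth_label = truth_label
  )
}

read_tsv_or_gz <- function(dir, base) {
  for (f in c(base, paste0(base, ".gz"))) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing ", base, "[.gz] in ", dir)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' each optionally gzipped. The features file carries gene id in column 1 and
#' symbol in column 2 (symbol falls back to the id when absent).
#'
#' @param directory Path to the sample directory.
#' @param config An [analysis_config()] for the gene-class prefixes.
#' @return A list with `counts` (sparse genes x cells matrix) and `genes`
#'   (a [gene_table()] tibble).
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- count_matrix(matrix(c(1, 0, 0, 2, 5, 5), nrow = 3, byrow = TRUE),
#'                   gene_ids = c("g1", "mt-Nd1", "Hbb-bs"),
#'                   cell_ids = c("c1", "c2"))
#' write_10x_mtx(m, gene_table(rownames(m)), d)
#' x <- read_10x_mtx(d)
#' all(x$counts == m)
#' @export
read_10x_mtx <- function(directory, config = analysis_config()) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  mtx <- NULL
  for (f in c("matrix.mtx", "matrix.mtx.gz")) {
    p <- file.path(directory, f)
    if (file.exists(p)) mtx <- p
  }
  if (is.null(mtx)) stop("missing matrix.mtx[.gz] in ", directory)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file ", mtx,
                                         ": ", conditionMessage(e)))
  feat <- tryCatch(read_tsv_or_gz(directory, "features.tsv"),
                   error = function(e) read_tsv_or_gz(directory, "genes.tsv"))
  bc <- read_tsv_or_gz(directory, "barcodes.tsv")
  ft <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  bt <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(ft) != nrow(m)) {
    stop("dimension mismatch in ", directory, ": matrix has ", nrow(m),
         " rows but features file ", feat, " has ", nrow(ft), " lines")
  }
  if (nrow(bt) != ncol(m)) {
    stop("dimension mismatch in ", directory, ": matrix has ", ncol(m),
         " columns but barcodes file ", bc, " has ", nrow(bt), " lines")
  }
  symbols <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  genes <- gene_table(ft[[1]], symbols, config = config)
  counts <- count_matrix(m, gene_ids = genes$gene_id, cell_ids = bt[[1]])
  list(counts = counts, genes = genes)
}

#' Write a 10x-style MatrixMarket triplet directory
#'
#' The round trip `read_10x_mtx(write_10x_mtx(...))` is bit-exact on integer
#' counts.
#'
#' @param counts A genes x cells count matrix (see [count_matrix()]).
#' @param genes A [gene_table()] tibble matching the rows of `counts`.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_10x_mtx <- function(counts, genes, directory) {
  stopifnot(nrow(genes) == nrow(counts),
            all(genes$gene_id == rownames(counts)))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(directory, "matrix.mtx"))
  write.table(data.frame(genes$gene_id, genes$symbol),
              file.path(directory, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Merge per-sample count matrices without down-sampling
#'
#' Columns are concatenated unchanged; no rescaling or down-sampling is
#' applied, so the total UMI count equals the sum over the inputs. Cell
#' identifiers get a `-<k>` suffix (sample index) to guarantee uniqueness.
#'
#' @param samples A list; each element has `counts` (genes x cells matrix)
#'   and `cells` (a [cell_table()] tibble).
#' @return A list with merged `counts` and `cells`.
#' @export
merge_samples <- function(samples) {
  stopifnot(length(samples) >= 1)
  ref <- rownames(samples[[1]]$counts)
  for (i in seq_along(samples)) {
    if (!identical(rownames(samples[[i]]$counts), ref)) {
      stop("gene universe mismatch: sample ", i,
           " does not share the gene ordering of sample 1")
    }
  }
  mats <- vector("list", length(samples))
  cells <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    m <- samples[[i]]$counts
    ct <- samples[[i]]$cells
    stopifnot(identical(as.character(ct$cell_id), colnames(m)))
    new_ids <- paste0(colnames(m), "-", i)
    colnames(m) <- new_ids
    ct$cell_id <- new_ids
    mats[[i]] <- m
    cells[[i]] <- ct
  }
  list(counts = do.call(cbind, mats), cells = dplyr::bind_rows(cells))
}

#' Read a GMT gene-set file
#'
#' Tab-delimited lines: set name, description, then member symbols. Set names
#' must be unique and every set nonempty.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  empty <- lengths(sets) == 0
  if (any(empty)) {
    stop("empty gene set(s) in ", path, ": ",
         paste(names(sets)[empty], collapse = ", "))
  }
  structure(sets, class = c("gene_set_collection", "list"))
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets), all(lengths(sets) > 0))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' A TSV with columns `sample_id`, `path`, `condition` mapping each 10x
#' directory to its experimental condition.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet misses column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$condition), c("control", "cKO"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  tibble::as_tibble(df)
}
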